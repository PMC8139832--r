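#' Confocal detection volume
#'
#' 3-D Gaussian detection volume with lateral 1/e² radius `w0` and
#' structure parameter `S = z0/w0`; the effective volume is
#' \eqn{V_{eff} = \pi^{3/2} w_0^2 z_0}.
#'
#' @param w0 lateral 1/e² radius (µm).
#' @param S structure parameter (axial/lateral ratio), default 5.
#' @return Object of class `confocal_volume` with `w0`, `S`, `z0` (µm)
#'   and `V_eff` in femtolitres (1 µm³ = 1 fl).
#' @export
confocal_volume <- function(w0, S = 5) {
  stopifnot(w0 > 0, S > 0)
  z0 <- S * w0
  structure(list(w0 = w0, S = S, z0 = z0, V_eff = pi^1.5 * w0^2 * z0),
            class = "confocal_volume")
}

#' Calibrate the detection volume from a reference dye
#'
#' Given the fitted diffusion time of a reference dye of known diffusion
#' coefficient (Rhodamine 6G, \eqn{D = 280} µm²/s), recovers the lateral
#' radius via \eqn{w_0 = \sqrt{4 D_{ref} \tau_{D,ref}}}.
#'
#' @param tau_D_ref fitted diffusion time of the reference dye (s).
#' @param D_ref reference diffusion coefficient (µm²/s), default 280.
#' @param S structure parameter, default 5.
#' @return A [confocal_volume()].
#' @export
calibrate_volume <- function(tau_D_ref, D_ref = 280, S = 5) {
  stopifnot(tau_D_ref > 0, D_ref > 0, S > 0)
  confocal_volume(w0 = sqrt(4 * D_ref * tau_D_ref), S = S)
}

#' FCS model parameters
#'
#' @param N mean number of particles in the detection volume (NoP).
#' @param tau_fast diffusion time of the (fast) component (s).
#' @param tau_slow diffusion time of the slow component (s), two-component
#'   model only.
#' @param F_fast fraction of the fast component (0-1); 1 for the
#'   one-component model.
#' @param T_trip triplet (dark-state) fraction in [0, 1).
#' @param tau_trip triplet relaxation time (s).
#' @param model `"one_component"` ('T + 3D') or `"two_component"`
#'   ('T + 3D + 3D').
#' @return Object of class `fcs_params`.
#' @export
fcs_params <- function(N, tau_fast, tau_slow = NA_real_, F_fast = 1,
                       T_trip = 0, tau_trip = 1e-5,
                       model = c("one_component", "two_component")) {
  model <- match.arg(model)
  stopifnot(N > 0, tau_fast > 0, F_fast >= 0, F_fast <= 1,
            T_trip >= 0, T_trip < 1, tau_trip > 0)
  if (model == "two_component") {
    stopifnot(is.finite(tau_slow), tau_slow > 0)
    if (tau_slow < tau_fast)
      stop("two-component model requires tau_fast < tau_slow")
  }
  structure(list(N = N, tau_fast = tau_fast, tau_slow = tau_slow,
                 F_fast = F_fast, T_trip = T_trip, tau_trip = tau_trip,
                 model = model),
            class = "fcs_params")
}

#' FCS autocorrelation model G(τ)
#'
#' Autocorrelation of free 3-D diffusion through a Gaussian detection
#' volume with an optional triplet component:
#' \deqn{G(\tau) = 1 + \frac{T(\tau)}{N} \sum_i F_i
#'   \left(1 + \tau/\tau_i\right)^{-1}
#'   \left(1 + \tau/(S^2 \tau_i)\right)^{-1/2},}
#' with triplet factor
#' \eqn{T(\tau) = 1 + \frac{T_{trip}}{1 - T_{trip}} e^{-\tau/\tau_{trip}}}.
#' One term ('T + 3D') for the one-component model, two terms with
#' fractions `F_fast` and `1 - F_fast` ('T + 3D + 3D') for the
#' two-component model.
#'
#' @param tau lag times (s).
#' @param params an [fcs_params()].
#' @param vol a [confocal_volume()] supplying the structure parameter.
#' @return Numeric vector of G(τ) values.
#' @export
fcs_model <- function(tau, params, vol) {
  stopifnot(inherits(params, "fcs_params"), inherits(vol, "confocal_volume"))
  if (params$T_trip >= 1) stop("triplet fraction must be below 1")
  S2 <- vol$S^2
  comp <- function(td) (1 + tau / td)^-1 * (1 + tau / (S2 * td))^-0.5
  diff_part <- if (params$model == "one_component") {
    comp(params$tau_fast)
  } else {
    params$F_fast * comp(params$tau_fast) +
      (1 - params$F_fast) * comp(params$tau_slow)
  }
  trip <- 1 + (params$T_trip / (1 - params$T_trip)) * exp(-tau / params$tau_trip)
  1 + trip * diff_part / params$N
}

#' FCS correlation curve
#'
#' @param tau lag times (s), strictly increasing and positive.
#' @param G autocorrelation values.
#' @param sd optional per-lag standard deviations used as fit weights.
#' @return Data frame of class `correlation_curve` with columns `tau_s`,
#'   `G` and optionally `sd`.
#' @export
correlation_curve <- function(tau, G, sd = NULL) {
  stopifnot(length(tau) == length(G), all(tau > 0), all(diff(tau) > 0),
            all(is.finite(G)))
  out <- data.frame(tau_s = tau, G = G)
  if (!is.null(sd)) {
    stopifnot(length(sd) == length(tau), all(sd > 0))
    out$sd <- sd
  }
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' Fit an FCS model to a correlation curve
#'
#' Weighted nonlinear least squares of the 'T + 3D' (one-component) or
#' 'T + 3D + 3D' (two-component) model over log-spaced lags, with
#' multi-start from bounded random initializations. Weights are `1/sd²`
#' when the curve carries per-lag standard deviations, unit otherwise.
#' Reports the least-squares AIC, \eqn{n \ln(SSE/n) + 2k} (`k` = number
#' of free parameters), used for model comparison via ΔAIC.
#'
#' Fitted diffusion times are converted to diffusion coefficients via
#' \eqn{D = w_0^2 / (4 \tau_D)}. If the fitted components come out
#' inverted (`tau_fast > tau_slow`) they are swapped and `F_fast`
#' complemented, so `D_fast >= D_slow` always holds.
#'
#' @param curve a [correlation_curve()] (≥ 10 lags spanning ≥ 3 decades).
#' @param model `"one_component"` or `"two_component"`.
#' @param vol a [confocal_volume()]; its structure parameter is held
#'   fixed during fitting.
#' @param fit_triplet if `TRUE`, the triplet fraction and relaxation time
#'   are free parameters; otherwise fixed at 0.
#' @param n_starts number of random initializations (first start is a
#'   heuristic guess from the curve).
#' @param seed integer seed for the random starts.
#' @return Object of class `fcs_fit`: list with `params`
#'   ([fcs_params()]), `D_fast`, `D_slow`, `aic`, `sse`, `r2`, `n`,
#'   `k`, `model`, `converged`, `excluded` (FALSE; see [qc_filter()])
#'   and the fitted curve.
#' @export
fit_fcs <- function(curve, model = c("one_component", "two_component"),
                    vol, fit_triplet = FALSE, n_starts = 5, seed = 1) {
  model <- match.arg(model)
  stopifnot(inherits(curve, "correlation_curve"), inherits(vol, "confocal_volume"))
  tau <- curve$tau_s; G <- curve$G
  if (length(tau) < 10L || log10(max(tau) / min(tau)) < 3)
    stop("correlation curve must have >= 10 lags spanning >= 3 decades")
  amp <- max(G) - 1
  if (amp < 1e-6)
    stop("no correlation amplitude (G ~ 1 everywhere): particle number unbounded, fit failure")
  w <- if ("sd" %in% names(curve)) 1 / curve$sd^2 else rep(1, length(tau))

  # bounds (log10 space for N and taus)
  lb <- c(lN = log10(1e-3), ltf = log10(1e-6))
  ub <- c(lN = log10(1e4), ltf = log10(1))
  if (model == "two_component") {
    lb <- c(lb, lts = log10(1e-6), F_fast = 0)
    ub <- c(ub, lts = log10(1), F_fast = 1)
  }
  if (fit_triplet) {
    lb <- c(lb, T_trip = 0, ltt = log10(1e-6))
    ub <- c(ub, T_trip = 0.5, ltt = log10(1e-2))
  }

  make_params <- function(p) {
    tf <- 10^p[["ltf"]]
    ts <- if (model == "two_component") 10^p[["lts"]] else NA_real_
    Ff <- if (model == "two_component") p[["F_fast"]] else 1
    if (model == "two_component" && ts < tf) { tmp <- tf; tf <- ts; ts <- tmp; Ff <- 1 - Ff }
    fcs_params(N = 10^p[["lN"]], tau_fast = tf, tau_slow = ts, F_fast = Ff,
               T_trip = if (fit_triplet) p[["T_trip"]] else 0,
               tau_trip = if (fit_triplet) 10^p[["ltt"]] else 1e-5,
               model = model)
  }
  residfun <- function(p) {
    pr <- p
    # allow unsorted taus during search; sort inside make_params
    prm <- tryCatch(make_params(pr), error = function(e) NULL)
    if (is.null(prm)) return(rep(1e6, length(G)))
    sqrt(w) * (G - fcs_model(tau, prm, vol))
  }

  # heuristic first start: amplitude -> N, half-decay lag -> tau
  N0 <- 1 / amp
  i_half <- which.min(abs((G - 1) - amp / 2))
  t_half <- tau[i_half]
  start0 <- c(lN = log10(N0), ltf = log10(t_half))
  if (model == "two_component")
    start0 <- c(start0, lts = log10(min(t_half * 30, 0.5)), F_fast = 0.5)
  if (fit_triplet) start0 <- c(start0, T_trip = 0.1, ltt = log10(1e-5))

  starts <- list(start0)
  rs <- .with_preserved_seed(seed, function() {
    lapply(seq_len(max(0, n_starts - 1)), function(i)
      stats::setNames(stats::runif(length(lb), lb, ub), names(lb)))
  })
  starts <- c(starts, rs)

  best <- NULL
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lb, upper = ub, fn = residfun,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(f)) next
    sse <- sum(f$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = f, sse = sse)
  }
  if (is.null(best))
    stop("FCS fit failed to converge from all starts")

  p <- best$fit$par
  params <- make_params(p)
  pred <- fcs_model(tau, params, vol)
  gof <- goodness_of_fit(G, pred)
  k <- length(p)
  n <- length(tau)
  aic <- n * log(gof$sse / n) + 2 * k
  structure(
    list(params = params,
         D_fast = vol$w0^2 / (4 * params$tau_fast),
         D_slow = if (params$model == "two_component")
           vol$w0^2 / (4 * params$tau_slow) else NA_real_,
         aic = aic, sse = gof$sse, r2 = gof$r2, n = n, k = k,
         model = model, vol = vol,
         converged = best$fit$info %in% 1:4,
         excluded = FALSE, exclude_reason = NA_character_,
         curve = curve, predicted = pred),
    class = "fcs_fit")
}

# run fn with a fixed seed, restoring the caller's RNG state afterwards
.with_preserved_seed <- function(seed, fn) {
  old <- .Random.seed_exists()
  if (old$exists) on.exit(assign(".Random.seed", old$value, envir = globalenv()))
  set.seed(seed)
  fn()
}

#' Choose between one- and two-component FCS fits by AIC
#'
#' The fit with the lower least-squares AIC wins; an exact tie is broken
#' toward the model with fewer parameters (parsimony).
#'
#' @param fit_1,fit_2 `fcs_fit` objects fitted to the identical curve.
#' @return The chosen `fcs_fit`, with `delta_aic` (|AIC difference|)
#'   attached.
#' @export
select_model <- function(fit_1, fit_2) {
  stopifnot(inherits(fit_1, "fcs_fit"), inherits(fit_2, "fcs_fit"))
  if (!isTRUE(all.equal(fit_1$curve$tau_s, fit_2$curve$tau_s)) ||
      !isTRUE(all.equal(fit_1$curve$G, fit_2$curve$G)))
    stop("model selection requires fits to the identical curve")
  d <- fit_1$aic - fit_2$aic
  chosen <- if (d < 0) fit_1
  else if (d > 0) fit_2
  else if (fit_1$k <= fit_2$k) fit_1 else fit_2
  chosen$delta_aic <- abs(d)
  chosen
}

#' Quality-filter FCS fits
#'
#' Applies the exclusion rules used when summarizing in-embryo FCS
#' measurements: fits with `D_fast` above `d_max` (80 µm²/s by default;
#' such values reflect fluorophore blinking rather than diffusion) are
#' excluded, and two-component fits whose components are degenerate
#' (`D_fast / D_slow` below `d_ratio_min`, making `F_fast` meaningless)
#' are excluded.
#'
#' @param fits a list of `fcs_fit` objects.
#' @param d_max maximum credible `D_fast` (µm²/s), default 80.
#' @param d_ratio_min minimum `D_fast / D_slow` separation for a
#'   two-component fit, default 3.
#' @return List with `kept` (list of fits) and `excluded` (list of fits,
#'   each with `excluded = TRUE` and an `exclude_reason`).
#' @export
qc_filter <- function(fits, d_max = 80, d_ratio_min = 3) {
  if (inherits(fits, "fcs_fit")) fits <- list(fits)
  kept <- list(); excluded <- list()
  for (f in fits) {
    reason <- NA_character_
    if (is.finite(f$D_fast) && f$D_fast > d_max) {
      reason <- sprintf("D_fast over threshold (%.3g > %.3g um2/s)", f$D_fast, d_max)
    } else if (f$model == "two_component" && is.finite(f$D_slow) &&
               f$D_fast / f$D_slow < d_ratio_min) {
      reason <- sprintf(
        "degenerate components (D_fast/D_slow = %.3g < %.3g): F_fast unreliable",
        f$D_fast / f$D_slow, d_ratio_min)
    }
    if (is.na(reason)) kept <- c(kept, list(f))
    else {
      f$excluded <- TRUE
      f$exclude_reason <- reason
      excluded <- c(excluded, list(f))
    }
  }
  list(kept = kept, excluded = excluded)
}

#' Multi-tau autocorrelation of an intensity trace
#'
#' Logarithmic-lag autocorrelation estimator with progressive binning:
#' the first octave evaluates lags `1..m` on the raw trace; each later
#' level halves the time resolution by averaging pairs of samples and
#' evaluates lags `m/2+1 .. m` in binned units. Symmetric normalization
#' is used at every lag:
#' \deqn{G(\tau_k) = \frac{\langle I_i I_{i+k} \rangle}
#'   {\langle I \rangle_{left} \langle I \rangle_{right}},}
#' with the two means taken over the actually overlapping segments.
#'
#' @param counts intensity (photon-count) trace.
#' @param dt sampling interval (s).
#' @param m channels per octave (default 16, even).
#' @param min_len stop binning when the binned trace gets shorter than
#'   this (default `4 * m`).
#' @return A [correlation_curve()] with lags `tau_s` and `G`.
#' @export
autocorrelate <- function(counts, dt, m = 16, min_len = 4 * m) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) >= 2 * m, m %% 2 == 0, dt > 0)
  if (mean(counts) <= 0)
    stop("trace mean is not positive; cannot normalize the correlation")

  g_at <- function(x, k) {
    M <- length(x)
    left <- x[1:(M - k)]; right <- x[(k + 1):M]
    mean(left * right) / (mean(left) * mean(right))
  }

  tau <- numeric(0); G <- numeric(0)
  x <- counts; level <- 0L
  repeat {
    lags <- if (level == 0L) 1:m else (m / 2 + 1):m
    width <- 2^level
    for (k in lags) {
      if (length(x) - k < 2) break
      tau <- c(tau, k * width * dt)
      G <- c(G, g_at(x, k))
    }
    # bin pairs of samples for the next octave
    M2 <- floor(length(x) / 2)
    if (M2 < min_len) break
    x <- (x[seq(1, 2 * M2, by = 2)] + x[seq(2, 2 * M2, by = 2)]) / 2
    level <- level + 1L
  }
  correlation_curve(tau, G)
}
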