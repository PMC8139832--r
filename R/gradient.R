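#' Extract bound-component peak values at docking sites
#'
#' For each docking site inside `x_range`, returns the maximum of the
#' bound field `v` over the site's nodes and the position of that
#' maximum. Sites where `v` is identically zero are retained with
#' `v_peak = 0`.
#'
#' @param state a [ligand_state()].
#' @param grid the matching [spatial_grid()].
#' @param binding a [binding_profile()] with at least two sites in range.
#' @param x_range numeric length-2 `c(x_min, x_max)` (µm); a site is in
#'   range when its peak position falls in `(x_min, x_max]`.
#' @return Data frame of class `peak_series` with columns `site_index`,
#'   `x_peak`, `v_peak`, ordered by position.
#' @export
extract_bound_peaks <- function(state, grid, binding,
                                x_range = c(0, grid$L)) {
  si <- binding$site_intervals
  if (nrow(si) == 0L) stop("binding profile has no docking sites")
  tol <- grid$dx * 1e-6
  rows <- lapply(seq_len(nrow(si)), function(k) {
    idx <- which(grid$x >= si$x_start[k] - tol & grid$x <= si$x_end[k] + tol)
    if (length(idx) == 0L) return(NULL)
    j <- idx[which.max(state$v[idx])]
    data.frame(site_index = si$site[k], x_peak = grid$x[j],
               v_peak = state$v[j])
  })
  peaks <- do.call(rbind, rows)
  keep <- peaks$x_peak > x_range[1] + tol & peaks$x_peak <= x_range[2] + tol
  peaks <- peaks[keep, , drop = FALSE]
  if (nrow(peaks) < 2L)
    stop("fewer than two docking sites inside x_range")
  rownames(peaks) <- NULL
  class(peaks) <- c("peak_series", "data.frame")
  peaks
}

#' Fit an exponential decay length to bound-peak values
#'
#' Nonlinear least squares of `v_peak` against `x_peak` for the
#' steady-gradient form \eqn{c(x) = c_0 \exp(-x/\lambda)}, with both the
#' amplitude and the decay length free. Fitting is performed on the
#' untransformed values; see [fit_decay_loglinear()] for the log-linear
#' cross-check estimator.
#'
#' Starting values: `c0` = first peak value; `lambda` =
#' `(x_last - x_first)/log(v_first/v_last)` when that is finite and
#' positive, else 10 µm.
#'
#' @param peaks a `peak_series` from [extract_bound_peaks()], or any data
#'   frame with columns `x_peak`, `v_peak` (≥ 3 positive peaks).
#' @return An object of class `decay_fit`: list with `c0`, `lambda`,
#'   `sse`, `r2`, `n_points`, `fit_range` and the residuals.
#' @export
fit_decay_length <- function(peaks) {
  x <- peaks$x_peak; y <- peaks$v_peak
  pos <- y > 0
  if (sum(pos) < 3L)
    stop("decay-length fit needs at least three positive peak values")
  x <- x[pos]; y <- y[pos]
  if (y[length(y)] >= y[1])
    stop("peak series does not decay over the fit range; exponential fit aborted")

  lam0 <- (x[length(x)] - x[1]) / log(y[1] / y[length(y)])
  if (!is.finite(lam0) || lam0 <= 0) lam0 <- 10
  fit <- minpack.lm::nlsLM(
    y ~ c0 * exp(-x / lambda),
    start = list(c0 = y[1], lambda = lam0),
    lower = c(1e-300, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  pred <- co[["c0"]] * exp(-x / co[["lambda"]])
  gof <- goodness_of_fit(y, pred)
  structure(
    list(c0 = co[["c0"]], lambda = co[["lambda"]], sse = gof$sse,
         r2 = gof$r2, n_points = length(y), fit_range = range(x),
         residuals = gof$residuals),
    class = "decay_fit")
}

#' Log-linear decay-length estimator (cross-check)
#'
#' Ordinary least squares of `log(v_peak)` on `x_peak`; the slope is
#' `-1/lambda`. Provided as an independent check on [fit_decay_length()];
#' it weights small peaks more heavily, so the two estimates differ
#' slightly on non-ideal data.
#'
#' @inheritParams fit_decay_length
#' @return List with `c0`, `lambda`, `r2`.
#' @export
fit_decay_loglinear <- function(peaks) {
  keep <- peaks$v_peak > 0
  x <- peaks$x_peak[keep]; y <- log(peaks$v_peak[keep])
  if (length(x) < 3L) stop("need at least three positive peaks")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  list(c0 = exp(co[[1]]), lambda = -1 / co[[2]],
       r2 = goodness_of_fit(y, stats::fitted(fit))$r2)
}

#' Closed-form homogenized decay length
#'
#' Spatially averaging the periodic docking-site profile gives mean
#' binding rate \eqn{\bar a = a_{max} p_2 / p_1}, and at steady state the
#' bound gradient decays with
#' \deqn{\lambda_{hom} = \sqrt{D (b + c) / (\bar a c)}.}
#' Used as an analytic oracle for the simulated decay length.
#'
#' @param kin a [kinetic_params()] (requires `c > 0`).
#' @param binding a periodic [binding_profile()].
#' @return The homogenized decay length (µm).
#' @export
homogenized_decay_length <- function(kin, binding) {
  if (binding$scenario != "periodic")
    stop("homogenized decay length is defined for the periodic scenario")
  if (kin$c <= 0)
    stop("homogenized decay length is infinite when internalization c = 0")
  a_bar <- binding$a_max * binding$p2 / binding$p1
  sqrt(kin$D * (kin$b + kin$c) / (a_bar * kin$c))
}

#' Normalize a profile or peak series to its maximum
#'
#' @param x a numeric vector, a [ligand_state()] (both fields normalized
#'   by the maximum of `v`), or a `peak_series` (normalizes `v_peak`).
#' @return Same shape as the input, scaled so the maximum is 1.
#' @export
normalize_profile <- function(x) {
  if (inherits(x, "ligand_state")) {
    m <- max(x$v)
    if (m <= 0) stop("cannot normalize: bound field is identically zero")
    x$v <- x$v / m
    x$u <- x$u / m
    return(x)
  }
  if (inherits(x, "peak_series") || (is.data.frame(x) && "v_peak" %in% names(x))) {
    m <- max(x$v_peak)
    if (m <= 0) stop("cannot normalize: all peak values are zero")
    x$v_peak <- x$v_peak / m
    return(x)
  }
  m <- max(x)
  if (m <= 0) stop("cannot normalize: maximum is not positive")
  x / m
}
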