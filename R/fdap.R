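#' FDAP time-intensity trace
#'
#' Container for a fluorescence-decay-after-photoconversion trace:
#' normalized red-channel intensity in the photoconverted strip, indexed
#' by post-conversion scan number. Frame `n` (starting at 1) is acquired
#' `n / fps` seconds after photoconversion.
#'
#' @param intensity normalized intensities (dimensionless).
#' @param fps frame rate (frames/s; default 25).
#' @param frame integer scan indices after photoconversion (default
#'   `1:length(intensity)`).
#' @param strip_width width of the photoconverted/measured strip (µm).
#' @param meta optional named list of extra metadata.
#' @return Data frame of class `fdap_trace` with columns `frame`,
#'   `time_s`, `intensity`; attributes `fps`, `strip_width`, `meta`.
#' @export
fdap_trace <- function(intensity, fps = 25, frame = seq_along(intensity),
                       strip_width = 1.66, meta = list()) {
  stopifnot(length(frame) == length(intensity), all(frame >= 1),
            all(diff(frame) > 0), all(is.finite(intensity)), fps > 0)
  out <- data.frame(frame = as.integer(frame), time_s = frame / fps,
                    intensity = as.numeric(intensity))
  attr(out, "fps") <- fps
  attr(out, "strip_width") <- strip_width
  attr(out, "meta") <- meta
  class(out) <- c("fdap_trace", "data.frame")
  out
}

#' Correct an FDAP trace for per-scan photobleaching
#'
#' Repeated laser scanning bleaches a fraction of the fluorophores on
#' every scan, so the measured trace is the true decay multiplied by
#' `q^n` (`n` = scan number after photoconversion). The correction
#' divides each intensity by `q^n`.
#'
#' @param trace an [fdap_trace()].
#' @param q per-scan retention factor in (0, 1]; the default 0.9991 is
#'   the repeated-scanning retention measured on fixed specimens.
#' @return The corrected `fdap_trace`; the applied `q` is recorded in the
#'   trace metadata.
#' @export
bleach_correct <- function(trace, q = 0.9991) {
  stopifnot(inherits(trace, "fdap_trace"))
  if (!is.numeric(q) || length(q) != 1L || q <= 0)
    stop("bleach retention factor q must be a positive scalar")
  out <- trace
  out$intensity <- trace$intensity / q^trace$frame
  meta <- attr(out, "meta")
  meta$bleach_corrected_q <- q
  attr(out, "meta") <- meta
  out
}

#' Estimate the per-scan bleaching factor from a fixed control
#'
#' Least-squares fit of `intensity[n] = q^n` to a trace measured on an
#' immobilized (fixed) specimen, where all signal loss is photobleaching.
#'
#' @param trace an [fdap_trace()] from a fixed control.
#' @param clip if `TRUE`, a fitted `q > 1` (rising trace) is clipped to 1
#'   after a warning; if `FALSE` (default) only the warning is issued.
#' @return List with `q`, `sse`, `r2`.
#' @export
fit_bleach_control <- function(trace, clip = FALSE) {
  stopifnot(inherits(trace, "fdap_trace"))
  n <- trace$frame; y <- trace$intensity
  fit <- minpack.lm::nlsLM(y ~ q^n, start = list(q = 0.999),
                           lower = 1e-6, upper = 1.5,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  q <- stats::coef(fit)[["q"]]
  if (q > 1 + 1e-8) {
    warning("fitted bleaching factor q > 1 (rising trace)")
    if (clip) q <- 1
  }
  gof <- goodness_of_fit(y, q^n)
  list(q = q, sse = gof$sse, r2 = gof$r2)
}

#' Fit the dissociation-kinetics model to an FDAP trace
#'
#' Fits the reaction-dominant decay
#' \deqn{I(t) = C + (1 - C) e^{-k_{off} t}}
#' to a bleach-corrected trace normalized to 1 at the moment of
#' photoconversion. `k_off` is the dissociation rate of the bound ligand
#' from its cell-surface scaffold and `C` the immobile fraction that does
#' not decay on the measurement timescale.
#'
#' A trace with negligible decay (range of intensities below `flat_tol`)
#' makes `k_off` unidentifiable; the fit then returns `k_off = 0`,
#' `C` = mean intensity, with `degenerate = TRUE`.
#'
#' @param trace a bleach-corrected [fdap_trace()].
#' @param flat_tol intensity range below which the trace is treated as
#'   flat (default 1e-6).
#' @return Object of class `dissociation_fit`: list with `k_off`, `C`,
#'   `sse`, `r2`, `max_abs_residual`, `frac_within_0.05`,
#'   `frac_within_0.10`, `degenerate` and the residuals.
#' @export
fit_dissociation <- function(trace, flat_tol = 1e-6) {
  stopifnot(inherits(trace, "fdap_trace"))
  t <- trace$time_s; y <- trace$intensity

  if (diff(range(y)) < flat_tol) {
    res <- y - mean(y)
    return(structure(
      list(k_off = 0, C = mean(y), sse = sum(res^2), r2 = NA_real_,
           max_abs_residual = max(abs(res)),
           frac_within_0.05 = mean(abs(res) <= 0.05),
           frac_within_0.10 = mean(abs(res) <= 0.10),
           degenerate = TRUE, residuals = res),
      class = "dissociation_fit"))
  }

  C0 <- max(min(mean(utils::tail(y, max(5L, length(y) %/% 10))), 0.999), 0)
  k0 <- 0.5 / stats::median(t)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ C + (1 - C) * exp(-k_off * t),
      start = list(C = C0, k_off = k0),
      lower = c(0, 0), upper = c(1, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("dissociation fit did not converge: ", conditionMessage(e)))
  co <- stats::coef(fit)
  pred <- co[["C"]] + (1 - co[["C"]]) * exp(-co[["k_off"]] * t)
  gof <- goodness_of_fit(y, pred)
  structure(
    list(k_off = co[["k_off"]], C = co[["C"]], sse = gof$sse, r2 = gof$r2,
         max_abs_residual = max(abs(gof$residuals)),
         frac_within_0.05 = mean(abs(gof$residuals) <= 0.05),
         frac_within_0.10 = mean(abs(gof$residuals) <= 0.10),
         degenerate = FALSE, residuals = gof$residuals),
    class = "dissociation_fit")
}

# mean labelled concentration remaining in a strip of full width W after a
# top-hat initial condition diffusing on an infinite line:
#   I(t) = erf(W/s) - (s/(W*sqrt(pi)))*(1 - exp(-W^2/s^2)),  s = sqrt(4 D t)
.strip_diffusion_decay <- function(t, D, W) {
  s <- sqrt(4 * D * t)
  out <- numeric(length(t))
  zero <- s <= 0 | D <= 0
  out[zero] <- 1
  sz <- s[!zero]
  z <- W / sz
  out[!zero] <- .erf(z) - (1 / (z * sqrt(pi))) * (1 - exp(-z^2))
  out
}

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Fit the effective-diffusion model to an FDAP trace
#'
#' Treats the loss of photoconverted signal as one-dimensional diffusion
#' with a single apparent coefficient `D_a`: the photoconverted strip is a
#' top-hat initial condition, and the readout is the mean labelled
#' concentration remaining in the same strip,
#' \deqn{I(t) = \mathrm{erf}(W/s) - \frac{s}{W\sqrt{\pi}}\left(1 - e^{-W^2/s^2}\right),
#'   \quad s = \sqrt{4 D_a t},}
#' where `W` is the full strip width. For ligands retarded by
#' binding/unbinding this `D_a` is an effective coefficient far below the
#' free-diffusion value. Optionally an immobile offset is added:
#' `I(t) = C + (1 - C) I_diff(t)`.
#'
#' @param trace a bleach-corrected [fdap_trace()].
#' @param strip_halfwidth half-width of the photoconverted strip (µm);
#'   default from the trace's `strip_width` attribute (1.66/2 µm).
#' @param immobile if `TRUE`, also fit an immobile fraction `C`.
#' @return Object of class `effective_diffusion_fit`: list with `D_a`,
#'   `C` (0 when not fitted), `sse`, `r2`, residual diagnostics.
#' @export
fit_effective_diffusion <- function(trace,
                                    strip_halfwidth = attr(trace, "strip_width") / 2,
                                    immobile = FALSE) {
  stopifnot(inherits(trace, "fdap_trace"), strip_halfwidth > 0)
  t <- trace$time_s; y <- trace$intensity
  if (stats::cor(t, y) > 0)
    stop("trace does not decay; effective-diffusion fit aborted")
  W <- 2 * strip_halfwidth

  # moment-based start: I drops to ~0.5 when sqrt(4 D t) ~ W
  t_half <- t[which.min(abs(y - (max(y) + min(y)) / 2))]
  D0 <- max(W^2 / (4 * t_half), 1e-6)

  if (immobile) {
    fit <- minpack.lm::nlsLM(
      y ~ C + (1 - C) * .strip_diffusion_decay(t, D_a, W),
      start = list(D_a = D0, C = max(min(y), 0)),
      lower = c(1e-9, 0), upper = c(Inf, 1),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    fit <- minpack.lm::nlsLM(
      y ~ .strip_diffusion_decay(t, D_a, W),
      start = list(D_a = D0), lower = 1e-9,
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  co <- stats::coef(fit)
  C <- if (immobile) co[["C"]] else 0
  pred <- C + (1 - C) * .strip_diffusion_decay(t, co[["D_a"]], W)
  gof <- goodness_of_fit(y, pred)
  structure(
    list(D_a = co[["D_a"]], C = C, sse = gof$sse, r2 = gof$r2,
         max_abs_residual = max(abs(gof$residuals)),
         residuals = gof$residuals),
    class = "effective_diffusion_fit")
}

#' Goodness-of-fit diagnostics
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return List with `sse` (sum of squared errors), `r2` (coefficient of
#'   determination, `1 - SSE / SStot`) and the `residuals`
#'   (observed - predicted).
#' @export
goodness_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  res <- observed - predicted
  sse <- sum(res^2)
  sstot <- sum((observed - mean(observed))^2)
  r2 <- if (sstot > 0) 1 - sse / sstot else NA_real_
  list(sse = sse, r2 = r2, residuals = res)
}
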