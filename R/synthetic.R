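#' Synthetic FDAP trace with bleaching and noise
#'
#' Generates a photoconversion decay with two-state exchange kinetics,
#' per-scan photobleaching and additive Gaussian noise:
#' \deqn{I_n = \left(C + (1 - C) e^{-k_{off} n / fps}\right) q^n + \epsilon_n,
#'   \quad \epsilon_n \sim N(0, \sigma^2),}
#' for scans `n = 1..n_frames` after photoconversion.
#'
#' @param k_off dissociation rate (1/s).
#' @param C immobile fraction (0-1).
#' @param q per-scan bleaching retention factor (default 0.9991).
#' @param fps frame rate (default 25 frames/s).
#' @param n_frames number of post-conversion frames (default 400, i.e.
#'   16 s at 25 fps).
#' @param noise_sd additive noise standard deviation.
#' @param seed integer seed; identical seeds give bit-identical traces.
#' @return An [fdap_trace()].
#' @export
gen_fdap_trace <- function(k_off, C, q = 0.9991, fps = 25, n_frames = 400,
                           noise_sd = 0, seed = 1) {
  stopifnot(k_off >= 0, C >= 0, C <= 1, q > 0, noise_sd >= 0)
  n <- seq_len(n_frames)
  clean <- (C + (1 - C) * exp(-k_off * n / fps)) * q^n
  eps <- if (noise_sd > 0)
    .with_preserved_seed(seed, function() stats::rnorm(n_frames, 0, noise_sd))
  else numeric(n_frames)
  fdap_trace(clean + eps, fps = fps,
             meta = list(generator = "gen_fdap_trace", k_off = k_off, C = C,
                         q = q, noise_sd = noise_sd, seed = seed))
}

#' Synthetic fixed-specimen bleaching control
#'
#' Pure per-scan photobleaching decay `q^n` plus additive noise,
#' emulating an immobilized (fixed) specimen under repeated scanning.
#'
#' @inheritParams gen_fdap_trace
#' @return An [fdap_trace()].
#' @export
gen_fixed_control <- function(q = 0.9991, fps = 25, n_frames = 400,
                              noise_sd = 0, seed = 1) {
  gen_fdap_trace(k_off = 0, C = 1, q = q, fps = fps, n_frames = n_frames,
                 noise_sd = noise_sd, seed = seed)
}

#' Configuration for a Brownian-dynamics FCS simulation
#'
#' Point emitters random-walk in a periodic box enclosing a 3-D Gaussian
#' detection volume; the recorded trace is Poisson photon counts per
#' sampling interval. The box must comfortably contain the detection
#' volume: lateral edges at least `6 w0` and the axial edge at least
#' `6 z0` (a scalar `box` gives a cube and must satisfy both).
#'
#' @param n_particles number of particles in the box.
#' @param D_values diffusion coefficient(s), one or two (µm²/s).
#' @param fractions per-species particle fractions (sums to 1).
#' @param box periodic box edges (µm): scalar (cube) or length-3
#'   `c(x, y, z)`; default `c(6 w0, 6 w0, 6 z0)`.
#' @param w0 lateral 1/e² radius of the detection volume (µm).
#' @param S structure parameter, default 5.
#' @param brightness molecular brightness (counts/particle/s).
#' @param dt sampling interval (s); must resolve the fastest diffusion
#'   time (`dt <= tau_fast / 10`).
#' @param duration trace length (s).
#' @param T_trip,tau_trip optional triplet blinking (equilibrium dark
#'   fraction and relaxation time); 0 disables blinking.
#' @return Object of class `brownian_config`.
#' @export
brownian_config <- function(n_particles, D_values, fractions = NULL,
                            box = NULL, w0 = 0.25, S = 5,
                            brightness = 3e4, dt = NULL, duration = 10,
                            T_trip = 0, tau_trip = 2e-6) {
  stopifnot(n_particles >= 1, all(D_values >= 0), length(D_values) %in% 1:2,
            w0 > 0, S > 0, brightness > 0, duration > 0,
            T_trip >= 0, T_trip < 1, tau_trip > 0)
  if (is.null(fractions)) fractions <- rep(1 / length(D_values), length(D_values))
  stopifnot(length(fractions) == length(D_values),
            abs(sum(fractions) - 1) < 1e-9, all(fractions >= 0))
  z0 <- S * w0
  # default lateral edge 10*w0: the box-size relaxation time then exceeds
  # ~10 diffusion times, so the periodic images do not visibly truncate the
  # slow 3-D tail of G(tau) (a 6*w0 box biases fitted D upward by ~15%)
  if (is.null(box)) box <- c(10 * w0, 10 * w0, 6 * z0)
  if (length(box) == 1L) box <- rep(box, 3)
  stopifnot(length(box) == 3L)
  if (box[1] < 6 * w0 || box[2] < 6 * w0)
    stop("lateral box edges must be at least 6 * w0")
  if (box[3] < 6 * z0)
    stop("axial box edge must be at least 6 * z0 to contain the detection volume")
  tau_fast <- if (any(D_values > 0)) w0^2 / (4 * max(D_values)) else Inf
  if (is.null(dt)) dt <- min(tau_fast / 10, 1e-4)
  if (dt > tau_fast / 10 + 1e-15)
    stop(sprintf("dt too coarse for fastest species: need dt <= tau_fast/10 = %.3g s",
                 tau_fast / 10))
  structure(list(n_particles = as.integer(n_particles), D_values = D_values,
                 fractions = fractions, box = box, w0 = w0, S = S, z0 = z0,
                 brightness = brightness, dt = dt, duration = duration,
                 T_trip = T_trip, tau_trip = tau_trip),
            class = "brownian_config")
}

#' Expected FCS particle number for a Brownian configuration
#'
#' Mean occupancy of the effective detection volume,
#' `n_particles / box_volume * V_eff`; this is the `N` that an FCS fit
#' of the simulated trace estimates.
#'
#' @param cfg a [brownian_config()].
#' @return Expected particle number (dimensionless).
#' @export
expected_occupancy <- function(cfg) {
  vol <- confocal_volume(cfg$w0, cfg$S)
  cfg$n_particles / prod(cfg$box) * vol$V_eff
}

#' Simulate a Brownian-dynamics FCS photon trace
#'
#' Runs the compiled random-walk/photon-emission simulation described in
#' [brownian_config()]. Reproducible: the same seed gives a bit-identical
#' trace.
#'
#' @param cfg a [brownian_config()].
#' @param seed integer seed.
#' @return List of class `fcs_trace` with `t_s` (sample times), `counts`
#'   (photon counts per interval), `dt` and the `cfg`.
#' @export
gen_brownian_fcs <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "brownian_config"))
  n_steps <- as.integer(round(cfg$duration / cfg$dt))
  n_species <- round(cfg$n_particles * cfg$fractions)
  # keep total particle count fixed
  n_species[1] <- cfg$n_particles - sum(n_species[-1])
  D_particle <- rep(cfg$D_values, times = n_species)
  counts <- .with_preserved_seed(seed, function()
    brownian_trace_cpp(D_particle, cfg$box[1], cfg$box[2], cfg$box[3],
                       cfg$w0, cfg$z0, cfg$brightness, cfg$dt, n_steps,
                       cfg$T_trip, cfg$tau_trip))
  structure(list(t_s = seq_len(n_steps) * cfg$dt, counts = counts,
                 dt = cfg$dt, cfg = cfg),
            class = "fcs_trace")
}

#' Add multiplicative lognormal noise to a peak series
#'
#' Robustness generator for decay-length fitting: each `v_peak` is
#' multiplied by an independent lognormal factor with median 1 and
#' log-scale `noise_sd`.
#'
#' @param peaks a `peak_series` (or data frame with `v_peak`).
#' @param noise_sd standard deviation of the log noise (0 = identity).
#' @param seed integer seed.
#' @return The perturbed peak series.
#' @export
gen_noisy_gradient <- function(peaks, noise_sd, seed = 1) {
  stopifnot(noise_sd >= 0)
  if (noise_sd == 0) return(peaks)
  fac <- .with_preserved_seed(seed, function()
    exp(stats::rnorm(nrow(peaks), 0, noise_sd)))
  peaks$v_peak <- peaks$v_peak * fac
  peaks
}
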