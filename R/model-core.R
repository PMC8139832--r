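#' Uniform 1-D spatial grid
#'
#' Builds the discretization of the extracellular domain \eqn{[0, L]} on
#' which the two-state ligand model is integrated.
#'
#' @param L domain length (µm).
#' @param dx spatial step (µm).
#' @return An object of class `spatial_grid` with fields `L`, `dx`,
#'   `n_points` and node positions `x` (with `x[1] = 0`, `x[n] = L`).
#' @export
spatial_grid <- function(L, dx) {
  stopifnot(is.numeric(L), length(L) == 1L, L > 0,
            is.numeric(dx), length(dx) == 1L, dx > 0)
  n_points <- as.integer(round(L / dx)) + 1L
  structure(
    list(L = L, dx = dx, n_points = n_points,
         x = seq(0, by = dx, length.out = n_points)),
    class = "spatial_grid"
  )
}

#' Kinetic parameters of the two-state ligand model
#'
#' @param D free-diffusion coefficient of the unbound ligand (µm²/s).
#' @param b release (dissociation) rate from docking sites (1/s).
#' @param c internalization rate of the bound component (1/s).
#' @param g_max production rate within the source region (amount/s).
#' @param R source half-width: production is active on `0 <= x <= R` (µm).
#' @param dt integration time step (s).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(D = 20, b = 0.1, c = 0.1, g_max = 0.2,
                           R = 1, dt = 1e-4) {
  stopifnot(D >= 0, b >= 0, c >= 0, g_max >= 0, R > 0, dt > 0)
  structure(list(D = D, b = b, c = c, g_max = g_max, R = R, dt = dt),
            class = "kinetic_params")
}

#' Check the explicit-scheme stability condition
#'
#' The forward-difference scheme is stable only when
#' \eqn{D \Delta t / \Delta x^2 < 1/2}.
#'
#' @param grid a [spatial_grid()].
#' @param kin a [kinetic_params()].
#' @param error if `TRUE` (default) an unstable configuration raises an
#'   error naming the stability number; otherwise the number is returned.
#' @return The stability number `D*dt/dx^2`, invisibly when `error = TRUE`.
#' @export
check_stability <- function(grid, kin, error = TRUE) {
  s <- kin$D * kin$dt / grid$dx^2
  if (error && s >= 0.5)
    stop(sprintf(
      "explicit scheme unstable: D*dt/dx^2 = %.4g >= 0.5 (reduce dt or D, or coarsen less)",
      s))
  if (error) invisible(s) else s
}

#' Docking-site binding-rate profile a(x)
#'
#' Builds the heterogeneous binding-rate field describing discrete
#' cell-surface docking sites (heparan-sulfate clusters). Site `n`
#' occupies the half-open interval `[p1*n, p1*n + p2)` for `n = 1, 2, ...` while it
#' fits in the domain; the binding rate is `a_max` (or a per-site random
#' amplitude) on a site and 0 elsewhere.
#'
#' Scenarios:
#' \describe{
#'   \item{`periodic`}{every site has amplitude `a_max`.}
#'   \item{`random_halfnormal`}{per-site amplitudes are drawn
#'     independently as `|Normal(0, sigma)|` with
#'     `sigma = a_max * sqrt(pi/2)`, so the half-normal mean equals
#'     `a_max`; requires `seed` for reproducibility.}
#'   \item{`band`}{amplitude `a_max` only for sites inside the window
#'     `band = c(x_start, x_end)`, 0 outside it.}
#'   \item{`absent_beyond`}{amplitude `a_max` for `x <= band[2]`
#'     (sites exist only up to a cut-off; `band[1]` defaults to 0).}
#'   \item{`zero`}{no docking sites, `a(x) = 0` everywhere.}
#' }
#'
#' @param grid a [spatial_grid()].
#' @param scenario one of `"periodic"`, `"random_halfnormal"`, `"band"`,
#'   `"absent_beyond"`, `"zero"`.
#' @param a_max site amplitude (1/s); for `random_halfnormal` the mean of
#'   the half-normal amplitude distribution.
#' @param p1 site interval (µm); must exceed `p2`.
#' @param p2 site width (µm).
#' @param band numeric length-2 window `c(x_start, x_end)` (µm), used by
#'   the `band` and `absent_beyond` scenarios.
#' @param seed integer seed, mandatory for `random_halfnormal`.
#' @return An object of class `binding_profile` with the per-node rate
#'   field `a`, the scenario label, per-site amplitudes `a_site` and the
#'   site intervals (data frame with `site`, `x_start`, `x_end`).
#' @export
binding_profile <- function(grid, scenario = c("periodic", "random_halfnormal",
                                               "band", "absent_beyond", "zero"),
                            a_max = 10, p1 = 2, p2 = 0.2, band = NULL,
                            seed = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(grid, "spatial_grid"))
  a <- numeric(grid$n_points)

  if (scenario == "zero" || a_max == 0) {
    return(structure(
      list(a = a, scenario = "zero", a_max = 0, p1 = p1, p2 = p2,
           a_site = numeric(0),
           site_intervals = data.frame(site = integer(0), x_start = numeric(0),
                                       x_end = numeric(0))),
      class = "binding_profile"))
  }

  stopifnot(a_max >= 0, p1 > 0, p2 > 0)
  if (p2 >= p1)
    stop("overlapping docking sites: site width p2 must be smaller than the interval p1")

  n_sites <- floor((grid$L - p2) / p1)
  if (n_sites < 1L) stop("domain too short for a single docking site")
  site <- seq_len(n_sites)
  x_start <- p1 * site
  x_end <- x_start + p2

  a_site <- rep(a_max, n_sites)
  if (scenario == "random_halfnormal") {
    if (is.null(seed))
      stop("random_halfnormal scenario requires a seed for reproducibility")
    old <- .Random.seed_exists()
    a_site <- local({
      if (old$exists) on.exit(assign(".Random.seed", old$value, envir = globalenv()))
      set.seed(seed)
      abs(stats::rnorm(n_sites, mean = 0, sd = a_max * sqrt(pi / 2)))
    })
  } else if (scenario %in% c("band", "absent_beyond")) {
    if (is.null(band)) stop(sprintf("scenario '%s' requires `band`", scenario))
    if (scenario == "absent_beyond" && length(band) == 1L) band <- c(0, band)
    stopifnot(length(band) == 2L, band[1] < band[2])
    if (band[1] < 0 || band[2] > grid$L)
      stop("band window lies outside the domain [0, L]")
    inside <- x_start >= band[1] - 1e-9 & x_end <= band[2] + 1e-9
    a_site[!inside] <- 0
  }

  # Half-open node alignment [x_start, x_end): a site of width p2 occupies
  # exactly p2/dx nodes, so the discretized mean binding rate equals the
  # continuum a_max*p2/p1 at any resolution. Closing both ends would add one
  # node per site and inflate the effective site width by dx.
  tol <- grid$dx * 1e-6
  for (k in site) {
    if (a_site[k] == 0) next
    idx <- which(grid$x >= x_start[k] - tol & grid$x < x_end[k] - tol)
    a[idx] <- a_site[k]
  }

  structure(
    list(a = a, scenario = scenario, a_max = a_max, p1 = p1, p2 = p2,
         a_site = a_site,
         site_intervals = data.frame(site = site, x_start = x_start,
                                     x_end = x_end)),
    class = "binding_profile")
}

# save/restore .Random.seed so profile construction does not disturb the
# caller's RNG stream
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    list(exists = TRUE, value = get(".Random.seed", envir = globalenv()))
  else list(exists = FALSE, value = NULL)
}

#' Ligand production profile g(x)
#'
#' Production at rate `g_max` confined to the source region
#' `0 <= x <= R`, zero elsewhere.
#'
#' @param grid a [spatial_grid()].
#' @param kin a [kinetic_params()] supplying `g_max` and `R`.
#' @return An object of class `source_profile` with the per-node field `g`.
#' @export
source_profile <- function(grid, kin) {
  stopifnot(inherits(grid, "spatial_grid"), inherits(kin, "kinetic_params"))
  if (kin$R > grid$L) stop("source half-width R exceeds the domain length L")
  # trapezoid-consistent sampling of the top-hat: full amplitude inside
  # [0, R), half at the edge node x = R, so the discrete influx (in the
  # trapezoidal mass functional the mirrored-ghost scheme conserves)
  # equals the continuum g_max*R exactly at any resolution
  tol <- grid$dx * 1e-6
  g <- ifelse(grid$x < kin$R - tol, kin$g_max,
              ifelse(grid$x < kin$R + tol, kin$g_max / 2, 0))
  structure(list(g = g), class = "source_profile")
}

#' Ligand state (free and bound fields)
#'
#' @param grid a [spatial_grid()].
#' @param u free-component field (defaults to 0).
#' @param v bound-component field (defaults to 0).
#' @param t elapsed time (s).
#' @return An object of class `ligand_state`.
#' @export
ligand_state <- function(grid, u = NULL, v = NULL, t = 0) {
  n <- grid$n_points
  if (is.null(u)) u <- numeric(n)
  if (is.null(v)) v <- numeric(n)
  stopifnot(length(u) == n, length(v) == n)
  structure(list(u = as.numeric(u), v = as.numeric(v), t = t),
            class = "ligand_state")
}

#' Single explicit-Euler step of the two-state model
#'
#' Pure-R reference implementation of one forward-difference update of
#' \deqn{\partial u/\partial t = D \partial^2 u/\partial x^2 - a(x) u + b v + g(x)}
#' \deqn{dv/dt = a(x) u - b v - c v}
#' with no-flux (Neumann) boundaries via mirrored ghost nodes. The bound
#' component does not diffuse. The compiled integrator used by
#' [simulate_ligand()] performs the identical update.
#'
#' @param state a [ligand_state()].
#' @param grid,kin,binding,source model components.
#' @return The updated `ligand_state` at `t + dt`.
#' @export
step_forward <- function(state, grid, kin, binding, source) {
  check_stability(grid, kin)
  u <- state$u; v <- state$v
  n <- grid$n_points
  stopifnot(length(u) == n, length(v) == n)
  a <- binding$a; g <- source$g

  lap <- numeric(n)
  lap[1] <- 2 * (u[2] - u[1])
  lap[n] <- 2 * (u[n - 1] - u[n])
  lap[2:(n - 1)] <- u[1:(n - 2)] - 2 * u[2:(n - 1)] + u[3:n]

  du <- kin$D * lap / grid$dx^2 - a * u + kin$b * v + g
  dv <- a * u - (kin$b + kin$c) * v
  ligand_state(grid, u + kin$dt * du, v + kin$dt * dv, t = state$t + kin$dt)
}

#' Integrate the two-state ligand model
#'
#' Runs the explicit forward-difference scheme (compiled core) from a zero
#' initial condition (or a supplied one) to `t_end`, recording snapshots.
#'
#' @param grid,kin,binding,source model components; `source` may be `NULL`
#'   for production-free runs.
#' @param t_end end time (s).
#' @param record_every snapshot interval (s); must be a multiple of `dt`.
#' @param init optional initial [ligand_state()] (default: `u = v = 0`).
#' @return An object of class `ligand_sim`: list with `times`, matrices
#'   `U` and `V` (snapshots in rows), the model components and the
#'   stability number. Use [final_state()] to extract the last snapshot.
#' @export
simulate_ligand <- function(grid, kin, binding, source = NULL,
                            t_end, record_every = t_end, init = NULL) {
  stopifnot(t_end > 0)
  check_stability(grid, kin)
  if (is.null(source)) {
    g <- numeric(grid$n_points)
  } else g <- source$g
  if (is.null(init)) init <- ligand_state(grid)
  n_steps <- as.integer(round(t_end / kin$dt))
  rec <- as.integer(round(record_every / kin$dt))
  if (rec < 1L || abs(rec * kin$dt - record_every) > 1e-9 * record_every)
    stop("record_every must be a positive multiple of dt")

  out <- euler_integrate_cpp(init$u, init$v, binding$a, g,
                             kin$D, kin$b, kin$c, grid$dx, kin$dt,
                             n_steps, rec)
  structure(
    list(times = out$times + init$t, U = out$U, V = out$V,
         grid = grid, kin = kin, binding = binding,
         stability = kin$D * kin$dt / grid$dx^2),
    class = "ligand_sim")
}

#' Extract a snapshot from a simulation
#'
#' @param sim a `ligand_sim` from [simulate_ligand()].
#' @param which snapshot index (default: the last).
#' @return A [ligand_state()].
#' @export
final_state <- function(sim, which = length(sim$times)) {
  ligand_state(sim$grid, sim$U[which, ], sim$V[which, ], t = sim$times[which])
}

#' Test whether a simulation has reached a near-steady state
#'
#' Compares snapshots within a trailing time window: steady iff the
#' maximum over nodes of `|Δfield| / (|field| + eps)` between the first
#' and last snapshot of the window is below `tol` for both fields.
#'
#' @param sim a `ligand_sim` with at least two snapshots in `window`.
#' @param window numeric length-2 time window `c(t_min, t_max)` (s).
#' @param tol relative-change tolerance.
#' @param eps regularizer protecting nodes far below the field maximum;
#'   `NULL` (default) uses `1e-4 * max(|field|)` per field, i.e. nodes
#'   holding less than a ten-thousandth of the peak amount cannot by
#'   themselves flag the run as transient.
#' @return A list with `steady` (logical) and `max_rel_change`.
#' @export
check_steady_state <- function(sim, window, tol = 1e-2, eps = NULL) {
  idx <- which(sim$times >= window[1] - 1e-9 & sim$times <= window[2] + 1e-9)
  if (length(idx) < 2L)
    stop("need at least two recorded snapshots inside the window")
  i0 <- idx[1]; i1 <- idx[length(idx)]
  rel_change <- function(f0, f1) {
    e <- if (is.null(eps)) 1e-4 * max(abs(f1), 1e-300) else eps
    max(abs(f1 - f0) / (abs(f1) + e))
  }
  m <- max(rel_change(sim$U[i0, ], sim$U[i1, ]),
           rel_change(sim$V[i0, ], sim$V[i1, ]))
  list(steady = m < tol, max_rel_change = m)
}

#' In-silico photoconversion of a steady ligand distribution
#'
#' Labels the sub-population inside `label_region` of a (near-)steady
#' state and follows both the labelled fields (same kinetics, no
#' production) and the total fields (with production). Because the model
#' is linear, the labelled sub-population obeys the same equations with
#' `g = 0`.
#'
#' @param steady a [ligand_state()] near steady state.
#' @param label_region numeric length-2 `c(x_start, x_end)` (µm).
#' @param grid,kin,binding,source model components.
#' @param t_end,record_every integration control (s).
#' @return A list of class `photoconversion_sim` with `times`, labelled
#'   snapshot matrices `U_lab`, `V_lab`, total matrices `U_tot`, `V_tot`,
#'   and `label_region`.
#' @export
simulate_photoconversion <- function(steady, label_region, grid, kin, binding,
                                     source, t_end, record_every = t_end) {
  stopifnot(length(label_region) == 2L, label_region[1] < label_region[2])
  if (label_region[1] < 0 || label_region[2] > grid$L)
    stop("label_region lies outside the domain [0, L]")
  inside <- grid$x >= label_region[1] - 1e-9 & grid$x <= label_region[2] + 1e-9
  lab0 <- ligand_state(grid, ifelse(inside, steady$u, 0),
                       ifelse(inside, steady$v, 0))
  lab <- simulate_ligand(grid, kin, binding, source = NULL,
                         t_end = t_end, record_every = record_every,
                         init = lab0)
  tot <- simulate_ligand(grid, kin, binding, source = source,
                         t_end = t_end, record_every = record_every,
                         init = steady)
  structure(
    list(times = lab$times, U_lab = lab$U, V_lab = lab$V,
         U_tot = tot$U, V_tot = tot$V, grid = grid,
         label_region = label_region),
    class = "photoconversion_sim")
}

#' Total free and bound mass
#'
#' Trapezoidal integrals of `u` and `v` over the domain.
#'
#' @param state a [ligand_state()].
#' @param grid the matching [spatial_grid()].
#' @return Named numeric vector `c(mass_u, mass_v)`.
#' @export
total_mass <- function(state, grid) {
  trap <- function(f) grid$dx * (sum(f) - (f[1] + f[length(f)]) / 2)
  c(mass_u = trap(state$u), mass_v = trap(state$v))
}
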