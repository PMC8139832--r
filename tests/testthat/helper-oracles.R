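# Independent brute-force oracles used to validate the package's fast paths.
# These deliberately use naive loops and direct formulas, not package code.

# One explicit-Euler step of the two-state model, node by node, with
# Neumann boundaries via explicit mirrored ghost values.
stencil_step_oracle <- function(u, v, a, g, D, b, c, dx, dt) {
  n <- length(u)
  un <- numeric(n); vn <- numeric(n)
  for (i in seq_len(n)) {
    um <- if (i == 1) u[2] else u[i - 1]   # ghost: u[0] := u[2]
    up <- if (i == n) u[n - 1] else u[i + 1]
    lap <- (um - 2 * u[i] + up) / dx^2
    un[i] <- u[i] + dt * (D * lap - a[i] * u[i] + b * v[i] + g[i])
    vn[i] <- v[i] + dt * (a[i] * u[i] - b * v[i] - c * v[i])
  }
  list(u = un, v = vn)
}

# Direct evaluation of the multi-tau estimand: block-average the raw trace
# with bin width `width`, then compute the symmetrically normalized
# correlation at lag `k` (in binned samples) by explicit summation.
direct_correlation_oracle <- function(counts, k, width = 1) {
  nb <- floor(length(counts) / width)
  xb <- numeric(nb)
  for (j in seq_len(nb))
    xb[j] <- mean(counts[((j - 1) * width + 1):(j * width)])
  M <- nb - k
  s <- 0
  for (i in seq_len(M)) s <- s + xb[i] * xb[i + k]
  ml <- sum(xb[1:M]) / M
  mr <- sum(xb[(k + 1):nb]) / M
  (s / M) / (ml * mr)
}

# trapezoidal integral on a uniform grid (for flux-balance checks)
trapz_oracle <- function(f, dx) dx * (sum(f) - (f[1] + f[length(f)]) / 2)
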