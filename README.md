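# gradexch

Modelling and measurement of extracellular dispersal of secreted
signalling ligands (Wnt8, Frzb and similar morphogens) that spread by
exchanging between a rare freely diffusing pool and an abundant pool bound
to discrete cell-surface docking sites (heparan-sulfate clusters).

The package is aimed at quantitative developmental biologists and
modellers who want to (i) simulate ligand gradients formed by bound/free
exchange, (ii) extract gradient decay lengths, and (iii) fit the two
photometric assays used to measure the underlying kinetics — fluorescence
decay after photoconversion (FDAP) and fluorescence correlation
spectroscopy (FCS) — including fully synthetic, seeded stand-ins for the
microscope so every stage is testable offline.

## The model

Free ligand $u(x,t)$ and bound ligand $v(x,t)$ on $[0, L]$ obey

$$\partial_t u = D\,\partial_x^2 u - a(x)\,u + b\,v + g(x), \qquad
  \partial_t v = a(x)\,u - (b + c)\,v,$$

with no-flux boundaries: production $g$ in a narrow source, diffusion $D$
of the free form only, binding $a(x)$ on discrete sites of width $p_2$
every $p_1$ µm, release $b$, internalization $c$. The bound gradient is
summarized by fitting site-peak values to $c_0 e^{-x/\lambda}$; spatial
averaging gives the closed-form check
$\lambda_\mathrm{hom} = \sqrt{D(b+c)/(\bar a c)}$ with
$\bar a = a_{\max} p_2/p_1$.

FDAP traces are corrected for per-scan photobleaching (÷ $q^n$,
$q = 0.9991$) and fitted with the dissociation model
$I(t) = C + (1-C)e^{-k_\mathrm{off}t}$ or a strip-diffusion model giving
an apparent coefficient $D_a$. FCS curves are fitted with 'T + 3D' /
'T + 3D + 3D' Gaussian-volume diffusion models, compared by AIC, and
quality-filtered ($D_\mathrm{fast} > 80$ µm²/s or degenerate component
pairs are excluded). A multi-tau correlator turns raw photon traces into
correlation curves.

See the methods vignette (`vignettes/ligand-gradient-methods.Rmd`) for the
full account of models, numerics and design choices.

## Worked example

Simulate the baseline scenario at reduced resolution and fit the decay
length of the bound-ligand gradient:

```r
library(gradexch)

res <- run_scenario(gradient_scenario("baseline", resolution = "reduced"))
res$fit$lambda
#> [1] 6.350132
homogenized_decay_length(res$sim$kin, res$sim$binding)
#> [1] 6.324555
```

The fitted decay length (6.35 µm) says the bound-ligand gradient falls by
1/e every ~6.3 µm — about one cell diameter — and agrees with the
homogenized closed form to 0.4%. Slower internalization lengthens the
gradient and removing dissociation shortens it:

```r
decay_length_scenarios(resolution = "reduced")
#>               scenario    lambda lambda_hom rel_diff_hom        r2 n_peaks
#> 1             baseline  6.350132   6.324555  0.004044022 1.0000000      50
#> 2 slow_internalization 10.787415  14.832397 -0.272712641 0.9993417      50
#> 3      no_dissociation  4.508877   4.472136  0.008215483 1.0000000      50
```

(The slow-internalization row is far from its homogenized value because
that scenario has not equilibrated at the 100-s protocol end time — see
the vignette.)

Fit a synthetic FDAP trace and an FCS curve:

```r
tr  <- gen_fdap_trace(k_off = 0.2, C = 0.7, q = 0.9991,
                      noise_sd = 0.02, seed = 1)
fit <- fit_dissociation(bleach_correct(tr, q = 0.9991))
c(k_off = fit$k_off, C = fit$C, r2 = fit$r2)
#>     k_off         C        r2 
#> 0.1997448 0.7007848 0.9145513

vol <- confocal_volume(w0 = 0.25, S = 5)
trace <- gen_brownian_fcs(brownian_config(n_particles = 250, D_values = 20,
                                          duration = 15), seed = 1)
fcs <- fit_fcs(autocorrelate(trace$counts, trace$dt), "one_component", vol)
c(N = fcs$params$N, D = fcs$D_fast)
#>         N         D 
#>  2.323047 20.447658
```

The FDAP fit recovers the generating off-rate (0.2/s) and immobile
fraction (0.7) from a noisy trace; the full Brownian-dynamics FCS pipeline
recovers the particle number expected in the 0.44-fl detection volume
(`expected_occupancy()` gives 2.32) and the generating diffusion
coefficient (20 µm²/s) to within a few percent.

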