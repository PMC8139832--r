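# Baseline two-state gradient scenario: rapid internalization of docking
# sites, reduced-resolution grid. Units: um, s.
L: 1000
dx: 0.2
dt: 4.0e-4
t_end: 100
record_every: 10
D: 20
b: 0.1
c: 0.1
g_max: 0.2
R: 1
scenario:
  kind: periodic
  a_max: 10
  p1: 2
  p2: 0.2
fit:
  x_min: 1
  x_max: 100
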