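# Symmetric anti-Hebbian LTD, scenario 1: a single LTD-only pathway.
# LTD establishes monotonically; no stimulation pattern reveals LTP.
calcium:
  c_pre: 7
  c_post: 7
  tau_ca: 17 ms
  delay_d: 0
pathways:
  - name: A
    gamma_p: 0      # no LTP mechanism
    gamma_d: 190
    theta0_p: inf
    theta0_d: 6
    mu_p: inf
    mu_d: inf
dynamics:
  tau: 280 s
  rho_star: 0.5
  sigma: 1
readout:
  ltp_star: 4
  ltd_star: 0.5
  slope: 0.5
thresholds:
  model: piecewise
  epsilon: 1
defaults:
  n_synapses: 1000
  steps_per_second: 2000   # 204000 Euler steps on the standard [-1, 101] s window
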