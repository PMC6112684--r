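# Classical asymmetric Hebbian STDP: a single pathway with no inactivation,
# LTP for pre-post pairings and LTD for post-pre pairings.
calcium:
  c_pre: 1
  c_post: 2
  tau_ca: 20 ms
  delay_d: 13.7 ms
pathways:
  - name: A
    gamma_p: 321.808
    gamma_d: 200
    theta0_p: 1.3
    theta0_d: 1
    mu_p: inf
    mu_d: inf
dynamics:
  tau: 150 s
  rho_star: 0.5
  sigma: 2.8284
readout:
  ltp_star: 4
  ltd_star: 0.5
  slope: 0.5
thresholds:
  model: piecewise
  epsilon: 1
defaults:
  n_synapses: 1000
  steps_per_second: 1000
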