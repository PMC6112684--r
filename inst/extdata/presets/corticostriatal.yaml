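# Cortico-striatal anti-Hebbian STDP: two pathways.
# eCB supports both LTP (inactivating at mu_p = 6, i.e. 14 pairings of the
# standard 1 Hz pair protocol) and LTD (never inactivating); NMDAR supports
# LTP only, inactivating at mu_p = 32 (74 pairings).
calcium:
  c_pre: 7          # calcium amplitude per presynaptic spike
  c_post: 17.1      # calcium amplitude per postsynaptic spike
  tau_ca: 18 ms     # calcium decay time constant
  delay_d: 10 ms    # delay of presynaptic calcium influx
pathways:
  - name: eCB
    gamma_p: 290    # eCB-LTP rate
    gamma_d: 250    # eCB-LTD rate
    theta0_p: 6     # eCB-LTP calcium threshold
    theta0_d: 13.5  # eCB-LTD calcium threshold
    mu_p: 6         # eCB-LTP inactivation level (concentration * s)
    mu_d: inf       # eCB-LTD active throughout
  - name: NMDAR
    gamma_p: 50
    gamma_d: 0      # no NMDAR-LTD mechanism
    theta0_p: 5.8
    theta0_d: inf
    mu_p: 32        # NMDAR-LTP inactivation level (74 pairings at 1 Hz)
    mu_d: inf
dynamics:
  tau: 165 s        # efficacy time constant
  rho_star: 0.5     # bistability midpoint
  sigma: 1          # noise intensity
readout:
  ltp_star: 3.475   # maximal potentiation
  ltd_star: 0.55    # maximal depression
  slope: 0.7        # sigmoid slope s
thresholds:
  model: piecewise
  epsilon: 1        # used only by the exponential threshold model
defaults:
  n_synapses: 1000
  steps_per_second: 1000   # 102000 Euler steps on the standard [-1, 101] s window
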