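# Band / window definitions for the six laminar signals.
# Times in seconds relative to the alignment event; bands in Hz.
signals:
  - name: visual_alpha_rdk
    event: RDK
    band: [7, 13]
    woi: [0, 2]
    baseline: [-1, -0.5]
    hypothesis: deep
  - name: visual_gamma_rdk
    event: RDK
    band: [60, 90]
    woi: [0.25, 0.5]
    baseline: [-0.5, -0.25]
    hypothesis: superficial
  - name: visual_gamma_cue
    event: cue
    band: [60, 90]
    woi: [0.1, 0.5]
    baseline: [-0.5, -0.1]
    hypothesis: superficial
  - name: sensorimotor_beta_rdk
    event: RDK
    band: [15, 30]
    woi: [0, 2]
    baseline: [-0.5, 0]
    hypothesis: deep
  - name: sensorimotor_beta_rebound
    event: response
    band: [15, 30]
    woi: [0.5, 1]
    baseline: [-0.25, 0.25]
    hypothesis: deep
  - name: sensorimotor_gamma_response
    event: response
    band: [60, 90]
    woi: [-0.1, 0.2]
    baseline: [-1.5, -1]
    hypothesis: superficial
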