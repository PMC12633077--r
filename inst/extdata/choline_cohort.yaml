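# Plasma choline recovery scenario: cosinor ground truth taken from a
# published wild-type plasma-choline rhythm (MESOR 36.34, amplitude
# 43.346, acrophase 15.649 h), sampled on the standard cross-sectional
# design (6 zeitgeber times at 4-h intervals, n = 8 mice per timepoint).
# noise_sd defaults to amplitude / 4.
period: 24
timepoints: [2, 6, 10, 14, 18, 22]
n_per_cell: [8]
features:
  - feature: plasma_choline
    group: WT
    mesor: 36.34
    amplitude: 43.346
    acrophase_h: 15.649
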