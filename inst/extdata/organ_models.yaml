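# Organ radiobiological parameter registry (configuration, not output).
#
# EUD volume-effect parameter `a`, linear-quadratic alpha/beta (Gy), and
# logistic NTCP parameters (td50_gy in EQD2 Gy for whole-organ uniform
# irradiation; gamma50 the normalized slope). Defaults follow the widely
# used photon-derived whole-organ tolerance fits (Burman/Emami lineage,
# a = 1/n); edit or replace this file to use institution-specific values.
total_lung:
  endpoint: pneumonitis
  a: 1.15          # near-parallel organ (n ~ 0.87)
  alpha_beta: 3.0
  td50_gy: 24.5
  gamma50: 2.0
heart:
  endpoint: pericarditis
  a: 2.9           # n ~ 0.35
  alpha_beta: 3.0
  td50_gy: 48.0
  gamma50: 3.0
esophagus:
  endpoint: esophagitis
  a: 16.7          # near-serial organ (n ~ 0.06)
  alpha_beta: 10.0
  td50_gy: 68.0
  gamma50: 4.0
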