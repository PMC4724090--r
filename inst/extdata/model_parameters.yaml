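# Published dose-response model parameter registry, v1.
# TCP: Poisson-LQ sets for NSCLC local control (D50 on the EQD2 scale,
# tumor alpha/beta 10 Gy). Lung LKB: pneumonitis grade >= 2 sets; the lung
# alpha/beta of 1.3 Gy is the default, with a 3 Gy variant for Seppenwoolde.
# lkb: other-organ LKB sets. seriality: relative-seriality (PLQ) sets.
tcp:
  willner_24mo: {d50_gy: 74.5, gamma: 3.5, alpha_beta_gy: 10}
  martel_24mo:  {d50_gy: 72.0, gamma: 2.0, alpha_beta_gy: 10}
  martel_30mo:  {d50_gy: 84.5, gamma: 1.5, alpha_beta_gy: 10}
lung_lkb:
  kwa:
    {d50_gy: 30.5, n_volume: 1.0, m_slope: 0.3, alpha_beta_gy: 1.3,
     endpoint: "pneumonitis grade >= 2"}
  seppenwoolde_ab1.3:
    {d50_gy: 30.8, n_volume: 0.99, m_slope: 0.37, alpha_beta_gy: 1.3,
     endpoint: "pneumonitis grade >= 2"}
  seppenwoolde_ab3:
    {d50_gy: 30.8, n_volume: 0.99, m_slope: 0.37, alpha_beta_gy: 3.0,
     endpoint: "pneumonitis grade >= 2"}
  burman:
    {d50_gy: 24.5, n_volume: 0.87, m_slope: 0.18, alpha_beta_gy: 1.3,
     endpoint: "pneumonitis grade >= 2"}
lkb:
  esophagus:
    {d50_gy: 51.0, n_volume: 0.44, m_slope: 0.32, alpha_beta_gy: 10,
     endpoint: "esophagitis grade >= 2"}
  heart:
    {d50_gy: 60.6, n_volume: 0.64, m_slope: 0.13, alpha_beta_gy: 2.5,
     endpoint: "pericarditis"}
seriality:
  cord_myelitis:
    {d50_gy: 68.6, gamma: 1.9, s_seriality: 4.0, alpha_beta_gy: 3,
     endpoint: "myelitis necrosis"}
  esophagus_stricture:
    {d50_gy: 68.6, gamma: 2.8, s_seriality: 3.4, alpha_beta_gy: 3,
     endpoint: "clinical stricture"}
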