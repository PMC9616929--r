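# SYNTHETIC placeholder disease specification for the 20-disease panel.
#
# target_auc values are the published predictor AUCs for this panel and are
# used by the cohort simulator as calibration anchors.  All other numbers
# (l: lifespan impact in years; rho: lifetime risk; pi: model prevalence;
# q: disability factor; delta_y: onset-to-death span in years) are synthetic
# placeholders of realistic magnitude for simulation and testing ONLY.
# They respect known qualitative constraints (l_MDD/l_AD ~ 1.6; near-zero
# weights for BCC and IBD; HA excluded from the case/control index because
# its case definition overlaps CAD).  Supply vetted literature values for
# any real-data analysis.
diseases:
  - {abbr: AD,   disease: "Alzheimer's disease",         l: 4.0,  rho: 0.10,  pi: 0.10,  q: 0.45, delta_y: 8,  sex: both,   in_cc_index: true,  target_auc: 0.686}
  - {abbr: AFib, disease: "Atrial fibrillation",         l: 3.0,  rho: 0.22,  pi: 0.22,  q: 0.20, delta_y: 12, sex: both,   in_cc_index: true,  target_auc: 0.623}
  - {abbr: ASA,  disease: "Asthma",                      l: 2.0,  rho: 0.15,  pi: 0.15,  q: 0.10, delta_y: 40, sex: both,   in_cc_index: true,  target_auc: 0.626}
  - {abbr: BC,   disease: "Breast cancer",               l: 3.0,  rho: 0.12,  pi: 0.12,  q: 0.30, delta_y: 15, sex: female, in_cc_index: true,  target_auc: 0.594}
  - {abbr: BCC,  disease: "Basal cell carcinoma",        l: 0.05, rho: 0.20,  pi: 0.20,  q: 0.05, delta_y: 20, sex: both,   in_cc_index: true,  target_auc: 0.62}
  - {abbr: CAD,  disease: "Coronary artery disease",     l: 8.0,  rho: 0.30,  pi: 0.30,  q: 0.30, delta_y: 15, sex: both,   in_cc_index: true,  target_auc: 0.616}
  - {abbr: Gout, disease: "Gout",                        l: 1.0,  rho: 0.04,  pi: 0.04,  q: 0.10, delta_y: 25, sex: both,   in_cc_index: true,  target_auc: 0.65}
  - {abbr: HA,   disease: "Heart attack",                l: 6.0,  rho: 0.12,  pi: 0.12,  q: 0.40, delta_y: 12, sex: both,   in_cc_index: false, target_auc: 0.580}
  - {abbr: HCL,  disease: "Hypercholesterolemia",        l: 2.5,  rho: 0.40,  pi: 0.40,  q: 0.05, delta_y: 30, sex: both,   in_cc_index: true,  target_auc: 0.616}
  - {abbr: HTN,  disease: "Hypertension",                l: 4.0,  rho: 0.45,  pi: 0.45,  q: 0.10, delta_y: 30, sex: both,   in_cc_index: true,  target_auc: 0.635}
  - {abbr: IBD,  disease: "Inflammatory bowel disease",  l: 0.3,  rho: 0.012, pi: 0.012, q: 0.20, delta_y: 40, sex: both,   in_cc_index: true,  target_auc: 0.647}
  - {abbr: IS,   disease: "Ischemic stroke",             l: 5.0,  rho: 0.15,  pi: 0.15,  q: 0.55, delta_y: 8,  sex: both,   in_cc_index: true,  target_auc: 0.541}
  - {abbr: MDD,  disease: "Major depressive disorder",   l: 6.4,  rho: 0.20,  pi: 0.20,  q: 0.40, delta_y: 35, sex: both,   in_cc_index: true,  target_auc: 0.534}
  - {abbr: MM,   disease: "Malignant melanoma",          l: 1.5,  rho: 0.025, pi: 0.025, q: 0.10, delta_y: 15, sex: both,   in_cc_index: true,  target_auc: 0.57}
  - {abbr: Obes, disease: "Obesity",                     l: 5.0,  rho: 0.30,  pi: 0.30,  q: 0.20, delta_y: 35, sex: both,   in_cc_index: true,  target_auc: 0.669}
  - {abbr: PC,   disease: "Prostate cancer",             l: 2.0,  rho: 0.12,  pi: 0.12,  q: 0.25, delta_y: 12, sex: male,   in_cc_index: true,  target_auc: 0.64}
  - {abbr: SCZ,  disease: "Schizophrenia",               l: 10.0, rho: 0.01,  pi: 0.01,  q: 0.70, delta_y: 40, sex: both,   in_cc_index: true,  target_auc: 0.67}
  - {abbr: T1D,  disease: "Type I diabetes",             l: 8.0,  rho: 0.01,  pi: 0.01,  q: 0.30, delta_y: 50, sex: both,   in_cc_index: true,  target_auc: 0.63}
  - {abbr: T2D,  disease: "Type II diabetes",            l: 6.0,  rho: 0.25,  pi: 0.25,  q: 0.25, delta_y: 20, sex: both,   in_cc_index: true,  target_auc: 0.616}
  - {abbr: TC,   disease: "Testicular cancer",           l: 0.5,  rho: 0.004, pi: 0.004, q: 0.10, delta_y: 45, sex: male,   in_cc_index: true,  target_auc: 0.61}
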