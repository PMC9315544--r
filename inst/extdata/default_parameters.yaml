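compounds:
  erlotinib:
    name: erlotinib
    log_p: 3.3
    pka: 5.5
    fu_plasma: 0.088
    bp_ratio: 0.95
    kd_egfr_nM: 2164.0
    base_class: weak
  afatinib:
    name: afatinib
    log_p: 3.6
    pka: 8.2
    fu_plasma: 0.095
    bp_ratio: 1.27
    kd_egfr_nM: 2.0
    base_class: strong
  osimertinib:
    name: osimertinib
    log_p: 3.2
    pka: 9.0
    fu_plasma: 0.017
    bp_ratio: 0.79
    kd_egfr_nM: 155.0
    base_class: strong
tissues:
  brain:
    name: brain
    f_nl: 0.039
    f_np: 0.0015
    f_ew: 0.16
    f_iw: 0.61
    ap_conc_mg_g: 0.4
    alb_ratio: 0.048
    egfr_nM: 0.0
    ph_ew: 7.4
    ph_iw: 7.0
    cell_types:
    - name: residual
      fraction: 1.0
      f_lys: 0.014
      ph_lys: 5.3
  lung:
    name: lung
    f_nl: 0.0088
    f_np: 0.003
    f_ew: 0.34
    f_iw: 0.43
    ap_conc_mg_g: 0.57
    alb_ratio: 0.21
    egfr_nM: 31.1
    ph_ew: 7.4
    ph_iw: 7.0
    cell_types:
    - name: alveolar_macrophages
      fraction: 0.041
      f_lys: 0.078
      ph_lys: 4.75
    - name: type_ii
      fraction: 0.083
      f_lys: 0.03
      ph_lys: 5.1
    - name: residual
      fraction: 0.876
      f_lys: 0.01
      ph_lys: 5.1
  spleen:
    name: spleen
    f_nl: 0.021
    f_np: 0.017
    f_ew: 0.21
    f_iw: 0.53
    ap_conc_mg_g: 3.18
    alb_ratio: 0.097
    egfr_nM: 54.6
    ph_ew: 7.4
    ph_iw: 7.0
    cell_types:
    - name: residual
      fraction: 1.0
      f_lys: 0.053
      ph_lys: 5.3
  kidney:
    name: kidney
    f_nl: 0.039
    f_np: 0.012
    f_ew: 0.27
    f_iw: 0.47
    ap_conc_mg_g: 2.44
    alb_ratio: 0.13
    egfr_nM: 177.0
    ph_ew: 7.4
    ph_iw: 7.0
    cell_types:
    - name: residual
      fraction: 1.0
      f_lys: 0.017
      ph_lys: 5.3
  bone:
    name: bone
    f_nl: 0.017
    f_np: 0.0017
    f_ew: 0.1
    f_iw: 0.35
    ap_conc_mg_g: 0.67
    alb_ratio: 0.1
    egfr_nM: 0.0
    ph_ew: 7.4
    ph_iw: 7.0
    cell_types: []
  tumor:
    name: tumor
    f_nl: 0.008
    f_np: 0.003
    f_ew: 0.34
    f_iw: 0.43
    ap_conc_mg_g: 0.57
    alb_ratio: 0.21
    egfr_nM: 299.0
    ph_ew: 6.7
    ph_iw: 7.0
    cell_types:
    - name: residual
      fraction: 1.0
      f_lys: 0.01
      ph_lys: 5.1
blood:
  hematocrit: 0.45
  ph_plasma: 7.4
  ph_bc: 7.22
  bc_f_iw: 0.6
  bc_f_nl: 0.0017
  bc_f_np: 0.0029
  bc_ap_mg_g: 0.5

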