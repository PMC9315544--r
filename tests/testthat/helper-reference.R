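# Shared fixtures: the default registry and the published reference values
# (predicted and PET-observed TBR, component shares) that the default
# parameterization is calibrated to reproduce.

ref_params <- default_parameters()
ref_blood <- ref_params$blood

ref_tissue_order <- c("brain", "lung", "spleen", "kidney", "bone", "tumor")

# reference predicted TBR of the calibrated model (rounded to print precision)
ref_predicted <- rbind(
  erlotinib   = c(0.13, 0.28, 0.17, 0.21, 0.14, 0.30),
  afatinib    = c(2.85, 6.89, 48.72, 26.20, 2.72, 15.36),
  osimertinib = c(1.52, 3.11, 25.33, 10.48, 1.48, 2.33))
colnames(ref_predicted) <- ref_tissue_order

# PET-image-derived observed TBR means (NA: not in field of view)
ref_observed <- rbind(
  erlotinib   = c(NA, 0.51, 1.46, 1.69, 1.23, 1.42),
  afatinib    = c(0.08, 2.54, 13.23, 6.93, 4.81, 3.60),
  osimertinib = c(0.79, 7.01, 18.09, 5.61, 4.24, 5.60))
colnames(ref_observed) <- ref_tissue_order

# reference component shares (%) of the final model in lung and tumor;
# NA marks components outside the compound's model class
ref_shares <- list(
  lung = rbind(
    egfr     = c(erlotinib = 0.21, afatinib = 16.73, osimertinib = 0.14),
    lysosome = c(NA, 49.19, 59.16),
    nl_np    = c(1.12, 0.01, 0.00),
    albumin  = c(73.01, NA, NA),
    ap_minus = c(NA, 32.63, 39.74),
    iw       = c(14.54, 1.08, 0.72),
    ew       = c(0.36, 0.36, 0.23)),
  tumor = rbind(
    egfr     = c(erlotinib = 1.89, afatinib = 72.17, osimertinib = 1.85),
    lysosome = c(NA, 11.99, 42.79),
    nl_np    = c(1.05, 0.00, 0.00),
    albumin  = c(72.32, NA, NA),
    ap_minus = c(NA, 14.63, 52.91),
    iw       = c(13.71, 0.48, 0.96),
    ew       = c(11.02, 0.73, 1.49)))

# long-form fixture of reference predicted/observed pairs (available only)
ref_pairs <- local({
  rows <- expand.grid(tissue = ref_tissue_order,
                      compound = rownames(ref_predicted),
                      stringsAsFactors = FALSE)
  rows$predicted <- mapply(function(cn, tn) ref_predicted[cn, tn],
                           rows$compound, rows$tissue)
  rows$observed <- mapply(function(cn, tn) ref_observed[cn, tn],
                          rows$compound, rows$tissue)
  rows[!is.na(rows$observed), c("compound", "tissue", "predicted", "observed")]
})
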