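# Frozen expected values below were computed by direct evaluation of the
# closed-form component formulas (see helper fixtures for the registry).

test_that("component terms match direct closed-form evaluation", {
  p <- ref_params; b <- ref_blood
  er <- p$compounds$erlotinib
  af <- p$compounds$afatinib
  os <- p$compounds$osimertinib
  lung <- p$tissues$lung; tum <- p$tissues$tumor; brain <- p$tissues$brain

  expect_equal(term_intracellular_water(er, lung), 0.43808266,
               tolerance = 1e-7)
  expect_equal(term_intracellular_water(af, lung), 0.99117148,
               tolerance = 1e-7)
  # neutral extracellular pH leaves the EW term at f_ew exactly
  expect_equal(term_extracellular_water(os, lung), 0.34)
  # acidic tumor microenvironment concentrates the strong base
  expect_equal(term_extracellular_water(os, tum), 1.6706131,
               tolerance = 1e-7)
  expect_equal(term_neutral_lipids(er, lung), 0.033685919, tolerance = 1e-7)
  expect_equal(term_neutral_lipids(af, lung), 0.0050645910, tolerance = 1e-7)
  no_lipid <- tissue_composition("x", 0, 0, 0.3, 0.4, 1, 1, 0, 7.4)
  expect_equal(term_neutral_lipids(af, no_lipid), 0)
  expect_equal(term_albumin(er, lung), 2.1763636, tolerance = 1e-7)
  expect_equal(term_albumin(er, brain), 0.49745455, tolerance = 1e-7)
  expect_equal(term_acidic_phospholipids(os, lung, b), 57.650317,
               tolerance = 1e-7)
  expect_equal(term_acidic_phospholipids(af, lung, b), 30.222773,
               tolerance = 1e-7)
  expect_equal(term_egfr(af, lung), 15.412716, tolerance = 1e-7)
  expect_equal(term_egfr(af, tum), 148.18014, tolerance = 1e-7)
  expect_equal(term_egfr(af, brain), 0)  # EGFR assumed absent
})

test_that("lysosome partition covers pH trapping plus membrane binding", {
  p <- ref_params; b <- ref_blood
  af <- p$compounds$afatinib; os <- p$compounds$osimertinib
  res <- p$tissues$tumor$cell_types[[1]]
  expect_equal(lysosome_partition(os, res, b, 0.57), 1929.0091,
               tolerance = 1e-7)
  expect_equal(lysosome_partition(af, res, b, 0.57, mode = "ph_only"),
               74.777761, tolerance = 1e-7)
  # no pH gradient, pH-only mode: no trapping
  neutral <- cell_type("x", 1, 0.01, 6.99)
  expect_equal(lysosome_partition(af, neutral, b, 0.57, ph_iw = 6.99,
                                  mode = "ph_only"), 1)
  expect_equal(term_lysosome(os, p$tissues$lung, b), 87.886322,
               tolerance = 1e-7)
  expect_equal(term_lysosome(af, p$tissues$tumor, b), 25.730467,
               tolerance = 1e-7)
  expect_equal(term_lysosome(af, p$tissues$bone, b), 0)  # no lysosomal data
})

test_that("model-class mismatches are rejected by name", {
  p <- ref_params; b <- ref_blood
  expect_error(term_albumin(p$compounds$afatinib, p$tissues$lung),
               "strong base")
  expect_error(term_acidic_phospholipids(p$compounds$erlotinib,
                                         p$tissues$lung, b), "weak base")
  expect_error(term_lysosome(p$compounds$erlotinib, p$tissues$lung, b),
               "weak base")
  expect_error(predict_tbr(p, "nosuch", "lung"), "unknown compound")
  expect_error(predict_tbr(p, "erlotinib", "nosuch"), "unknown tissue")
})

test_that("predicted TBR equals the rescaled component sum exactly", {
  p <- ref_params
  for (cn in names(p$compounds)) for (tn in names(p$tissues)) {
    pred <- predict_tbr(p, cn, tn)
    cmp <- p$compounds[[cn]]
    expect_equal(pred$tbr,
                 pred$coefficient * sum(pred$terms, na.rm = TRUE) *
                   cmp$fu_plasma / cmp$bp_ratio, tolerance = 1e-12)
    expect_equal(pred$total_unbound, sum(pred$terms, na.rm = TRUE),
                 tolerance = 1e-12)
    expect_equal(sum(pred$percentages, na.rm = TRUE), 100, tolerance = 1e-9)
    expect_true(all(pred$terms >= 0, na.rm = TRUE))
    expect_true(pred$tbr > 0)
  }
})

test_that("TBR increases strictly in each binding-site density", {
  base <- predict_tbr(ref_params, "afatinib", "lung")$tbr
  bump <- function(ov) predict_tbr(apply_overrides(ref_params, ov),
                                   "afatinib", "lung")$tbr
  expect_gt(bump(list(tissues = list(lung = list(egfr_nM = 40)))), base)
  expect_gt(bump(list(tissues = list(lung = list(ap_conc_mg_g = 0.8)))), base)
  expect_gt(bump(list(tissues = list(lung = list(cell_types = list(
    residual = list(f_lys = 0.02)))))), base)
  base_w <- predict_tbr(ref_params, "erlotinib", "lung")$tbr
  expect_gt(bump_alb <- predict_tbr(
    apply_overrides(ref_params,
                    list(tissues = list(lung = list(alb_ratio = 0.3)))),
    "erlotinib", "lung")$tbr, base_w)
})

test_that("membrane-mode lysosome term dominates pH-only mode everywhere", {
  p <- ref_params; b <- ref_blood
  for (cn in c("afatinib", "osimertinib")) for (tn in names(p$tissues)) {
    mem <- term_lysosome(p$compounds[[cn]], p$tissues[[tn]], b, "membrane")
    ph <- term_lysosome(p$compounds[[cn]], p$tissues[[tn]], b, "ph_only")
    expect_gte(mem, ph)
  }
})

test_that("tissue pH barely moves weak-base ionization factors", {
  grid <- expand.grid(pka = seq(3, 5.5, by = 0.25),
                      ph = seq(6.7, 7.6, by = 0.05))
  f <- ionization_factor(grid$pka, grid$ph, 7.4)
  expect_true(all(f >= 0.93 & f <= 1.08))
})

test_that("unit vasculature coefficient reproduces the final model exactly", {
  explicit <- scenario_config("explicit_unit_vasc", f_vasc = 1)
  for (cn in names(ref_params$compounds)) for (tn in c("lung", "tumor")) {
    expect_identical(predict_tbr(ref_params, cn, tn, explicit)$tbr,
                     predict_tbr(ref_params, cn, tn)$tbr)
  }
})

test_that("a tumor parameterized as lung returns the lung prediction", {
  p <- ref_params
  lung_copy <- p$tissues$lung
  lung_copy$name <- "tumor"
  p$tissues$tumor <- lung_copy
  neutral <- scenario_config("lungish_tumor", tumor_ph_ew = p$tissues$lung$ph_ew)
  for (cn in names(p$compounds)) {
    expect_identical(predict_tbr(p, cn, "tumor", neutral)$tbr,
                     predict_tbr(p, cn, "lung", neutral)$tbr)
  }
})

test_that("tumor-to-lung contrast is the ratio of the two predictions", {
  for (cn in names(ref_params$compounds)) {
    expect_equal(tumor_to_lung_contrast(ref_params, cn),
                 predict_tbr(ref_params, cn, "tumor")$tbr /
                   predict_tbr(ref_params, cn, "lung")$tbr,
                 tolerance = 1e-12)
  }
  # positive contrast for erlotinib/afatinib, negative for osimertinib
  expect_gt(tumor_to_lung_contrast(ref_params, "erlotinib"), 1)
  expect_gt(tumor_to_lung_contrast(ref_params, "afatinib"), 1)
  expect_lt(tumor_to_lung_contrast(ref_params, "osimertinib"), 1)
})

test_that("prediction grid is long-form with totals and shares", {
  grid <- predict_grid(ref_params)
  expect_setequal(unique(grid$component),
                  c("egfr", "lysosome", "nl_np", "albumin", "ap_minus", "iw",
                    "ew", "total"))
  totals <- grid[grid$component == "total", ]
  expect_equal(nrow(totals), 18)
  er_lung <- totals$value[totals$compound == "erlotinib" &
                            totals$tissue == "lung"]
  expect_equal(er_lung, 0.27737861, tolerance = 1e-7)
  # weak base rows carry albumin, no lysosome/AP-
  er <- grid[grid$compound == "erlotinib", "component"]
  expect_false(any(er %in% c("lysosome", "ap_minus")))
  expect_true("albumin" %in% er)
})
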