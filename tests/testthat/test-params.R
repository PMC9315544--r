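test_that("default registry carries the tabulated values", {
  p <- ref_params
  expect_named(p$compounds, c("erlotinib", "afatinib", "osimertinib"))
  expect_equal(p$compounds$osimertinib$pka, 9.0)
  expect_equal(p$compounds$afatinib$kd_egfr_nM, 2)
  expect_equal(p$compounds$erlotinib$base_class, "weak")
  expect_equal(p$compounds$afatinib$base_class, "strong")
  expect_equal(p$tissues$lung$ap_conc_mg_g, 0.57)
  expect_equal(p$tissues$bone$egfr_nM, 0)
  expect_equal(p$tissues$brain$egfr_nM, 0)
  expect_equal(p$tissues$tumor$egfr_nM, 299)
  expect_equal(p$tissues$tumor$ph_ew, 6.7)
  # tumor inherits lung's AP- and albumin values (hallmark-override design)
  expect_equal(p$tissues$tumor$ap_conc_mg_g, p$tissues$lung$ap_conc_mg_g)
  expect_equal(p$tissues$tumor$alb_ratio, p$tissues$lung$alb_ratio)
  expect_equal(p$blood$hematocrit, 0.45)
  expect_equal(p$blood$ph_bc, 7.22)
  # lung carries the three cell populations summing to 1
  lc <- p$tissues$lung$cell_types
  expect_length(lc, 3)
  expect_equal(sum(vapply(lc, `[[`, numeric(1), "fraction")), 1)
  # tumor: single residual population
  tc <- p$tissues$tumor$cell_types
  expect_length(tc, 1)
  expect_equal(tc[[1]]$f_lys, 0.01)
  expect_equal(tc[[1]]$ph_lys, 5.1)
  # bone has no lysosomal data
  expect_length(p$tissues$bone$cell_types, 0)
  # selectable tabulated lung extracellular pH
  expect_equal(default_parameters(lung_ph_ew = 7.22)$tissues$lung$ph_ew, 7.22)
})

test_that("every default value carries a non-empty provenance string", {
  p <- ref_params
  objs <- c(p$compounds, p$tissues, list(p$blood),
            p$tissues$lung$cell_types, p$tissues$tumor$cell_types)
  for (obj in objs) {
    prov <- attr(obj, "provenance")
    expect_true(length(prov) > 0)
    expect_true(all(nzchar(prov)))
  }
})

test_that("observed-TBR fixture has 18 records with one unavailable", {
  obs <- observed_tbr()
  expect_equal(nrow(obs), 18)
  expect_equal(sum(obs$available), 17)
  na_row <- obs[!obs$available, ]
  expect_equal(na_row$compound, "erlotinib")
  expect_equal(na_row$tissue, "brain")
  expect_equal(obs$mean[obs$compound == "afatinib" & obs$tissue == "brain"],
               0.08)
  expect_equal(obs$sd[obs$compound == "osimertinib" & obs$tissue == "spleen"],
               7.7)
  expect_true(all(obs$mean[obs$available] > 0))
  expect_true(all(obs$sd[obs$available] >= 0))
})

test_that("constructors reject invariant violations", {
  expect_error(compound_params("x", 3, 8, 1.5, 1, 1), "fu_plasma")
  expect_error(compound_params("x", 3, 8, 0.1, -1, 1), "bp_ratio")
  expect_error(compound_params("x", 3, 5, 0.1, 1, 1, base_class = "strong"),
               "inconsistent")
  expect_error(cell_type("x", 1.2, 0.01, 5), "fraction")
  expect_error(cell_type("x", 0.5, 0.01, 7.4), "ph_lys")
  expect_error(tissue_composition("x", 0.1, 0.1, 0.6, 0.5, 1, 1, 0, 7.4),
               "f_ew \\+ f_iw")
})

test_that("YAML serialization round-trips the default registry losslessly", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(ref_params, path)
  back <- read_parameters(path)
  expect_equal(rapply(unclass(ref_params), identity, how = "unlist"),
               rapply(unclass(back), identity, how = "unlist"))
  # shipped canonical defaults match the in-code registry
  shipped <- system.file("extdata", "default_parameters.yaml",
                         package = "pbpktbr")
  expect_true(nzchar(shipped))
  expect_equal(rapply(unclass(read_parameters(shipped)), identity,
                      how = "unlist"),
               rapply(unclass(ref_params), identity, how = "unlist"))
})

test_that("overrides deep-merge, validate, and reject unknown names", {
  # empty override is the identity
  expect_equal(apply_overrides(ref_params, list()), ref_params)
  # single-field merge changes only that field
  p2 <- apply_overrides(ref_params, list(
    compounds = list(erlotinib = list(fu_plasma = 0.176))))
  expect_equal(p2$compounds$erlotinib$fu_plasma, 0.176)
  p2$compounds$erlotinib <- NULL
  p1 <- ref_params
  p1$compounds$erlotinib <- NULL
  expect_equal(rapply(unclass(p1), identity, how = "unlist"),
               rapply(unclass(p2), identity, how = "unlist"))
  # cell-type override reaches the nested object
  p3 <- apply_overrides(ref_params, list(
    tissues = list(tumor = list(cell_types = list(
      residual = list(f_lys = 0.02))))))
  expect_equal(p3$tissues$tumor$cell_types[[1]]$f_lys, 0.02)
  # invariant violations and unknown names are rejected with diagnostics
  expect_error(apply_overrides(ref_params, list(
    compounds = list(erlotinib = list(fu_plasma = 1.5)))), "fu_plasma")
  expect_error(apply_overrides(ref_params, list(
    compounds = list(nosuch = list(pka = 8)))), "unknown compound")
  expect_error(apply_overrides(ref_params, list(
    tissues = list(lung = list(nosuch_field = 1)))), "unknown field")
})
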