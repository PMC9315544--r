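# Component terms of the unbound tissue-to-plasma partition coefficient
# (Kpu). Each term_* function returns one additive contribution on the
# unbound-partition scale; predict_tbr() sums the terms applicable to the
# compound's model class and rescales by fu/B:P to the tissue-to-blood ratio.

as_compound <- function(params, compound) {
  if (inherits(compound, "compound_params")) return(compound)
  if (!compound %in% names(params$compounds))
    stop("unknown compound '", compound, "'; known: ",
         paste(names(params$compounds), collapse = ", "), call. = FALSE)
  params$compounds[[compound]]
}

as_tissue <- function(params, tissue) {
  if (inherits(tissue, "tissue_composition")) return(tissue)
  if (!tissue %in% names(params$tissues))
    stop("unknown tissue '", tissue, "'; known: ",
         paste(names(params$tissues), collapse = ", "), call. = FALSE)
  params$tissues[[tissue]]
}

#' Intracellular-water partition term
#'
#' Ion trapping of a base in the (slightly acidic, pH 7.0) intracellular
#' water relative to plasma: `IF(pKa, pH_iw, pH_p) * f_iw`.
#'
#' @param compound A [compound_params()] object.
#' @param tissue A [tissue_composition()] object.
#' @param ph_plasma Plasma pH (7.4).
#' @return Unbound-partition contribution (>= 0).
#' @export
term_intracellular_water <- function(compound, tissue, ph_plasma = 7.4) {
  ionization_factor(compound$pka, tissue$ph_iw, ph_plasma) * tissue$f_iw
}

#' Extracellular-water partition term
#'
#' `IF(pKa, pH_ew, pH_p) * f_ew`; for the acidic tumor microenvironment
#' (pH_ew 6.7) this concentrates strong bases relative to plasma.
#'
#' @inheritParams term_intracellular_water
#' @return Unbound-partition contribution (>= 0).
#' @export
term_extracellular_water <- function(compound, tissue, ph_plasma = 7.4) {
  ionization_factor(compound$pka, tissue$ph_ew, ph_plasma) * tissue$f_ew
}

#' Neutral lipid and neutral phospholipid binding term
#'
#' `(P*f_nl + (0.3P + 0.7)*f_np) / (1 + 10^(pKa - pH_p))`: only the
#' unprotonated, lipophilic species binds the neutral lipids.
#'
#' @inheritParams term_intracellular_water
#' @param logp_convention See [lipophilicity_value()].
#' @return Unbound-partition contribution (>= 0).
#' @export
term_neutral_lipids <- function(compound, tissue, ph_plasma = 7.4,
                                logp_convention = c("direct", "power")) {
  p <- lipophilicity_value(compound$log_p, logp_convention)
  nl_np_numerator(p, tissue$f_nl, tissue$f_np) /
    (1 + 10^(compound$pka - ph_plasma))
}

#' Albumin binding term (weak-base model only)
#'
#' `(1/fu - 1) * alb_ratio`: plasma albumin binding scaled by the albumin
#' tissue-to-plasma ratio. The dominant tissue-binding process for a mostly
#' unprotonated weak base.
#'
#' @inheritParams term_intracellular_water
#' @return Unbound-partition contribution (>= 0).
#' @export
term_albumin <- function(compound, tissue) {
  if (compound$base_class != "weak")
    stop("albumin term belongs to the weak-base model; '", compound$name,
         "' is a strong base", call. = FALSE)
  albumin_binding_capacity(compound$fu_plasma) * tissue$alb_ratio
}

#' Acidic-phospholipid binding term (strong-base model only)
#'
#' `Ka * [AP-] * 10^(pKa - pH_iw) / (1 + 10^(pKa - pH_p))`, with Ka
#' calibrated from blood cells ([ap_association_constant()]). Only the
#' protonated species binds the negatively charged acidic phospholipids.
#'
#' @inheritParams term_neutral_lipids
#' @param blood A [blood_params()] object (calibration source for Ka).
#' @return Unbound-partition contribution (>= 0).
#' @export
term_acidic_phospholipids <- function(compound, tissue, blood,
                                      ph_plasma = 7.4,
                                      logp_convention = c("direct", "power")) {
  if (compound$base_class != "strong")
    stop("acidic-phospholipid term belongs to the strong-base model; '",
         compound$name, "' is a weak base", call. = FALSE)
  ka <- ap_association_constant(compound, blood, logp_convention)
  ka * tissue$ap_conc_mg_g * 10^(compound$pka - tissue$ph_iw) /
    (1 + 10^(compound$pka - ph_plasma))
}

#' EGFR target-binding term
#'
#' `([EGFR]/Kd) * IF(pKa, pH_iw, pH_p) * f_iw`: intracellular receptor
#' binding at the wild-type dissociation constant, scaled by the ionization
#' accumulation in intracellular water. Zero where EGFR is absent.
#'
#' @inheritParams term_intracellular_water
#' @return Unbound-partition contribution (>= 0).
#' @export
term_egfr <- function(compound, tissue, ph_plasma = 7.4) {
  if (compound$kd_egfr_nM <= 0) stop("kd_egfr_nM must be positive",
                                     call. = FALSE)
  (tissue$egfr_nM / compound$kd_egfr_nM) *
    ionization_factor(compound$pka, tissue$ph_iw, ph_plasma) * tissue$f_iw
}

#' Lysosome-to-cytosol partition coefficient of one cell population
#'
#' pH-driven trapping of the base in the acidic lysosome,
#' `IF(pKa, pH_lys, pH_iw)`, optionally plus binding to the lysosomal
#' membrane. The lysosomal membrane is assumed to share the composition of
#' the cell's outer membrane, so the membrane term reuses the
#' acidic-phospholipid machinery with the tissue's own AP- concentration:
#' `Ka * [AP-] * 10^(pKa - pH_lys) / (1 + 10^(pKa - pH_iw))`.
#'
#' @param compound A strong-base [compound_params()] object.
#' @param cell A [cell_type()] object.
#' @param blood A [blood_params()] object (Ka calibration).
#' @param membrane_ap_mg_g AP- concentration of the membrane, mg/g (the
#'   tissue's outer-membrane value).
#' @param ph_iw Cytosolic pH of the host tissue.
#' @param mode `"membrane"` or `"ph_only"`.
#' @param logp_convention See [lipophilicity_value()].
#' @return Unitless lysosome-to-cytosol coefficient Kpu_lys (>= 1 for a base
#'   in an acidic lysosome).
#' @export
lysosome_partition <- function(compound, cell, blood, membrane_ap_mg_g,
                               ph_iw = 7.0, mode = c("membrane", "ph_only"),
                               logp_convention = c("direct", "power")) {
  mode <- match.arg(mode)
  if (compound$base_class != "strong")
    stop("lysosomal sequestration belongs to the strong-base model; '",
         compound$name, "' is a weak base", call. = FALSE)
  kpu <- ionization_factor(compound$pka, cell$ph_lys, ph_iw)
  if (mode == "membrane") {
    ka <- ap_association_constant(compound, blood, logp_convention)
    kpu <- kpu + ka * membrane_ap_mg_g * 10^(compound$pka - cell$ph_lys) /
      (1 + 10^(compound$pka - ph_iw))
  }
  kpu
}

#' Lysosomal sequestration term of a tissue (strong-base model only)
#'
#' `IF(pKa, pH_iw, pH_p) * sum_celltypes(fraction * f_lys * Kpu_lys)`: the
#' cell-type-weighted lysosomal volume times the lysosome-to-cytosol
#' coefficient, carried to the plasma reference through the intracellular
#' ionization factor. Tissues with no lysosomal population return 0.
#'
#' @inheritParams term_acidic_phospholipids
#' @param mode `"membrane"` or `"ph_only"`, see [lysosome_partition()].
#' @return Unbound-partition contribution (>= 0).
#' @export
term_lysosome <- function(compound, tissue, blood,
                          mode = c("membrane", "ph_only"), ph_plasma = 7.4,
                          logp_convention = c("direct", "power")) {
  mode <- match.arg(mode)
  if (compound$base_class != "strong")
    stop("lysosomal term belongs to the strong-base model; '", compound$name,
         "' is a weak base", call. = FALSE)
  if (!length(tissue$cell_types)) return(0)
  per_cell <- vapply(tissue$cell_types, function(ct) {
    ct$fraction * ct$f_lys *
      lysosome_partition(compound, ct, blood, tissue$ap_conc_mg_g,
                         tissue$ph_iw, mode, logp_convention)
  }, numeric(1))
  ionization_factor(compound$pka, tissue$ph_iw, ph_plasma) * sum(per_cell)
}

# realize a tissue under a scenario: tumor hallmarks are scenario-driven
realize_tissue <- function(params, tissue_name, scenario) {
  tis <- as_tissue(params, tissue_name)
  if (identical(tis$name, "tumor")) {
    tis$ph_ew <- scenario$tumor_ph_ew
    if (!scenario$immune_deprivation)
      tis$cell_types <- params$tissues$lung$cell_types
  }
  tis
}

#' Predict the tissue-to-blood ratio of a tracer in a tissue
#'
#' Assembles the unbound tissue-to-plasma partition coefficient Kpu from the
#' component terms applicable to the compound's model class, applies any
#' tumor coefficient of the scenario, and rescales to the blood reference:
#'
#' * weak base (model 1): `TBR = coef * (IW + EW + NL/NP + ALB + EGFR) * fu/B:P`
#' * strong base (model 2): `TBR = coef * (IW + EW + NL/NP + AP- + LYS + EGFR) * fu/B:P`
#'
#' where `coef = f_vasc * f_perf` for tumor and 1 otherwise.
#'
#' @param params A [parameter_set][default_parameters()].
#' @param compound Compound name or [compound_params()] object.
#' @param tissue Tissue name or [tissue_composition()] object.
#' @param scenario A [scenario_config()]; default [final_model_scenario()].
#' @param logp_convention See [lipophilicity_value()].
#' @return An object of class `tbr_prediction`: list with `compound`,
#'   `tissue`, `scenario`, `terms` (named unbound-partition contributions;
#'   `NA` for components not in the compound's model), `total_unbound`,
#'   `tbr` and `percentages` (component shares of the total, in %).
#' @examples
#' p <- default_parameters()
#' predict_tbr(p, "erlotinib", "lung")$tbr    # ~0.28
#' predict_tbr(p, "osimertinib", "lung")$tbr  # ~3.2
#' @export
predict_tbr <- function(params, compound, tissue,
                        scenario = final_model_scenario(),
                        logp_convention = c("direct", "power")) {
  stopifnot(inherits(scenario, "tbr_scenario"))
  cmp <- as_compound(params, compound)
  tis <- realize_tissue(params, if (inherits(tissue, "tissue_composition"))
    tissue$name else tissue, scenario)
  blood <- params$blood
  ph_p <- blood$ph_plasma
  terms <- c(egfr = NA_real_, lysosome = NA_real_, nl_np = NA_real_,
             albumin = NA_real_, ap_minus = NA_real_, iw = NA_real_,
             ew = NA_real_)
  terms["iw"] <- term_intracellular_water(cmp, tis, ph_p)
  terms["ew"] <- term_extracellular_water(cmp, tis, ph_p)
  terms["nl_np"] <- term_neutral_lipids(cmp, tis, ph_p, logp_convention)
  if (cmp$base_class == "weak") {
    terms["albumin"] <- term_albumin(cmp, tis)
  } else {
    terms["ap_minus"] <- term_acidic_phospholipids(cmp, tis, blood, ph_p,
                                                   logp_convention)
    terms["lysosome"] <- term_lysosome(cmp, tis, blood,
                                       scenario$lysosome_mode, ph_p,
                                       logp_convention)
  }
  terms["egfr"] <- if (scenario$egfr_enabled) term_egfr(cmp, tis, ph_p) else 0
  total <- sum(terms, na.rm = TRUE)
  coef <- if (identical(tis$name, "tumor")) scenario$f_vasc * scenario$f_perf
          else 1
  structure(
    list(compound = cmp$name, tissue = tis$name, scenario = scenario$name,
         terms = terms, total_unbound = total,
         tbr = coef * total * cmp$fu_plasma / cmp$bp_ratio,
         coefficient = coef,
         percentages = terms / total * 100),
    class = "tbr_prediction")
}

#' @export
print.tbr_prediction <- function(x, digits = 4, ...) {
  cat(sprintf("%s / %s [scenario %s]: TBR = %s\n", x$compound, x$tissue,
              x$scenario, signif(x$tbr, digits)))
  shown <- x$terms[!is.na(x$terms)]
  pct <- x$percentages[names(shown)]
  for (nm in names(shown))
    cat(sprintf("  %-9s %12s  (%6.2f%%)\n", nm, signif(shown[[nm]], digits),
                pct[[nm]]))
  invisible(x)
}

#' Decompose a prediction into component contributions
#'
#' Same computation as [predict_tbr()], returned with the component
#' percentage shares as the headline result. Components outside the
#' compound's model class are `NA` (mirroring the published
#' not-applicable cells).
#'
#' @inheritParams predict_tbr
#' @return A `tbr_prediction` (see [predict_tbr()]); its `percentages` sum
#'   to 100 over the applicable components.
#' @export
decompose_tbr <- function(params, compound, tissue,
                          scenario = final_model_scenario(),
                          logp_convention = c("direct", "power")) {
  predict_tbr(params, compound, tissue, scenario, logp_convention)
}

#' Predicted tumor-to-lung contrast
#'
#' The image-quality surrogate: predicted tumor TBR divided by predicted
#' lung TBR.
#'
#' @inheritParams predict_tbr
#' @return Positive scalar.
#' @export
tumor_to_lung_contrast <- function(params, compound,
                                   scenario = final_model_scenario(),
                                   logp_convention = c("direct", "power")) {
  predict_tbr(params, compound, "tumor", scenario, logp_convention)$tbr /
    predict_tbr(params, compound, "lung", scenario, logp_convention)$tbr
}

#' Predict TBR over a compound-by-tissue grid
#'
#' @inheritParams predict_tbr
#' @param compounds,tissues Name vectors; default full registry in reporting
#'   order.
#' @return A long data.frame with one row per compound, tissue and component
#'   (`component = "total"` rows carry the TBR), columns `compound`,
#'   `tissue`, `scenario`, `component`, `value` (unbound-partition term, or
#'   TBR for totals) and `percent`.
#' @export
predict_grid <- function(params, compounds = names(params$compounds),
                         tissues = names(params$tissues),
                         scenario = final_model_scenario(),
                         logp_convention = c("direct", "power")) {
  rows <- list()
  for (cn in compounds) for (tn in tissues) {
    pred <- predict_tbr(params, cn, tn, scenario, logp_convention)
    keep <- !is.na(pred$terms)
    rows[[length(rows) + 1L]] <- data.frame(
      compound = cn, tissue = tn, scenario = scenario$name,
      component = c(names(pred$terms)[keep], "total"),
      value = c(unname(pred$terms[keep]), pred$tbr),
      percent = c(unname(pred$percentages[keep]), 100))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
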