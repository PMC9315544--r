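#' Scenario configuration for the partition model
#'
#' A scenario is a declarative switch-set over the mechanistic model: which
#' components are active and which tumor-hallmark coefficients apply. The
#' final model and its component ablations are all expressed this way.
#'
#' @param name Unique scenario label.
#' @param egfr_enabled Include the EGFR target-binding term?
#' @param lysosome_mode `"membrane"` (pH trapping plus lysosomal-membrane
#'   binding) or `"ph_only"` (pH trapping alone).
#' @param immune_deprivation If `TRUE` (final model), tumor tissue carries
#'   only its residual-cell lysosomal population; if `FALSE`, tumor receives
#'   the full lung cell-type mix (macrophages, type II, residual).
#' @param tumor_ph_ew Tumor extracellular-water pH (6.7 acidic hallmark, 7.4
#'   neutral).
#' @param f_vasc Vasculature coefficient applied to the tumor prediction
#'   (0.36 in the vascularized variant; 1 in the final model).
#' @param f_perf Perfusion coefficient applied to the tumor prediction
#'   (1: unaltered perfusion).
#' @return An object of class `tbr_scenario`.
#' @export
scenario_config <- function(name, egfr_enabled = TRUE,
                            lysosome_mode = c("membrane", "ph_only"),
                            immune_deprivation = TRUE, tumor_ph_ew = 6.7,
                            f_vasc = 1, f_perf = 1) {
  lysosome_mode <- match.arg(lysosome_mode)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (f_vasc <= 0 || f_perf <= 0)
    stop("scenario coefficients must be positive", call. = FALSE)
  structure(list(name = name, egfr_enabled = isTRUE(egfr_enabled),
                 lysosome_mode = lysosome_mode,
                 immune_deprivation = isTRUE(immune_deprivation),
                 tumor_ph_ew = tumor_ph_ew, f_vasc = f_vasc, f_perf = f_perf),
            class = "tbr_scenario")
}

#' The final mechanistic model scenario
#'
#' All components on: EGFR binding, membrane-mode lysosomal sequestration,
#' tumor immune deprivation, acidic tumor extracellular water (pH 6.7),
#' unaltered perfusion (`f_perf = 1`) and no vasculature coefficient
#' (`f_vasc = 1`).
#'
#' @return A `tbr_scenario`.
#' @export
final_model_scenario <- function() scenario_config("final")

#' Component-ablation scenario suite
#'
#' Five single-component ablations of the final model, one per sensitivity
#' analysis: `no_egfr`, `ph_only_lysosome`, `no_immune_deprivation` (tumor
#' gets the lung cell-type mix), `vascularized` (`f_vasc = 0.36` on tumor)
#' and `neutral_tumor_ew` (tumor extracellular pH back to 7.4). Each differs
#' from the final scenario in exactly one field.
#'
#' @return Named list of five `tbr_scenario` objects.
#' @export
ablation_suite <- function() {
  list(
    no_egfr = scenario_config("no_egfr", egfr_enabled = FALSE),
    ph_only_lysosome = scenario_config("ph_only_lysosome",
                                       lysosome_mode = "ph_only"),
    no_immune_deprivation = scenario_config("no_immune_deprivation",
                                            immune_deprivation = FALSE),
    vascularized = scenario_config("vascularized", f_vasc = 0.36),
    neutral_tumor_ew = scenario_config("neutral_tumor_ew", tumor_ph_ew = 7.4))
}

#' Look up a scenario by name
#'
#' @param name `"final"` or one of the [ablation_suite()] names.
#' @return A `tbr_scenario`.
#' @export
scenario_by_name <- function(name) {
  suite <- c(list(final = final_model_scenario()), ablation_suite())
  if (!name %in% names(suite))
    stop("unknown scenario '", name, "'; known: ",
         paste(names(suite), collapse = ", "), call. = FALSE)
  suite[[name]]
}

#' @export
print.tbr_scenario <- function(x, ...) {
  cat("scenario '", x$name, "': egfr=", x$egfr_enabled,
      ", lysosome=", x$lysosome_mode,
      ", immune_deprivation=", x$immune_deprivation,
      ", tumor_ph_ew=", x$tumor_ph_ew,
      ", f_vasc=", x$f_vasc, ", f_perf=", x$f_perf, "\n", sep = "")
  invisible(x)
}

#' Sensitivity analysis: final model versus each ablation
#'
#' For every scenario in the suite and every compound, recomputes the lung
#' and tumor predictions and the tumor-to-lung contrast under both the final
#' model and the ablated model, and reports the prediction error of each
#' against the observed PET values. The final-model column is recomputed
#' alongside each ablation, never cached.
#'
#' @param params A parameter set; defaults to [default_parameters()].
#' @param scenarios Scenario list; defaults to [ablation_suite()].
#' @param observed Observed-TBR table as from [observed_tbr()].
#' @param compounds Compound names to include.
#' @return A data.frame with columns `scenario`, `compound`, `quantity`
#'   (`"lung"`, `"tumor"`, `"contrast"`), `predicted_final`,
#'   `predicted_scenario`, `observed`, `pe_final`, `pe_scenario`. Pairs with
#'   no observed value are skipped with a message.
#' @export
run_sensitivity <- function(params = default_parameters(),
                            scenarios = ablation_suite(),
                            observed = observed_tbr(),
                            compounds = names(params$compounds)) {
  final <- final_model_scenario()
  rows <- list()
  for (sc in scenarios) {
    stopifnot(inherits(sc, "tbr_scenario"))
    for (cn in compounds) {
      pred <- function(s, tn) predict_tbr(params, cn, tn, s)$tbr
      lung_f <- pred(final, "lung");  lung_s <- pred(sc, "lung")
      tum_f <- pred(final, "tumor"); tum_s <- pred(sc, "tumor")
      obs_row <- function(tn) {
        i <- observed$compound == cn & observed$tissue == tn
        if (!any(i) || !observed$available[i]) NA_real_ else observed$mean[i]
      }
      obs <- c(lung = obs_row("lung"), tumor = obs_row("tumor"))
      quantities <- data.frame(
        quantity = c("lung", "tumor", "contrast"),
        predicted_final = c(lung_f, tum_f, tum_f / lung_f),
        predicted_scenario = c(lung_s, tum_s, tum_s / lung_s),
        observed = c(obs[["lung"]], obs[["tumor"]],
                     obs[["tumor"]] / obs[["lung"]]))
      skip <- is.na(quantities$observed)
      if (any(skip))
        message("run_sensitivity: no observed value for ", cn, " ",
                paste(quantities$quantity[skip], collapse = ", "),
                "; pair skipped")
      quantities <- quantities[!skip, , drop = FALSE]
      if (!nrow(quantities)) next
      quantities$pe_final <- prediction_error(quantities$predicted_final,
                                              quantities$observed)
      quantities$pe_scenario <- prediction_error(quantities$predicted_scenario,
                                                 quantities$observed)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(scenario = sc$name, compound = cn), quantities)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
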