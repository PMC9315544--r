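#' Compound parameter set for one tracer
#'
#' Bundles the physicochemical and target-binding constants that drive the
#' partition models: lipophilicity (log P), basicity (pKa), fraction unbound
#' in plasma, whole-blood to plasma concentration ratio and the dissociation
#' constant for wild-type EGFR.
#'
#' @param name Compound label, e.g. `"erlotinib"`.
#' @param log_p Octanol/water log-partition value (unitless).
#' @param pka Basicity constant (unitless).
#' @param fu_plasma Fraction unbound in plasma, in (0, 1].
#' @param bp_ratio Whole-blood to plasma concentration ratio (> 0).
#' @param kd_egfr_nM Dissociation constant for wild-type EGFR, nM (> 0).
#' @param base_class `"weak"` or `"strong"`; defaults to `"strong"` iff
#'   `pka > 7`, the boundary separating mostly-protonated from
#'   mostly-unprotonated compounds at physiological pH.
#' @param provenance Named character vector tracing each value to its source.
#' @return An object of class `compound_params`.
#' @export
compound_params <- function(name, log_p, pka, fu_plasma, bp_ratio, kd_egfr_nM,
                            base_class = if (pka > 7) "strong" else "weak",
                            provenance = character()) {
  stopifnot(is.character(name), length(name) == 1L)
  base_class <- match.arg(base_class, c("weak", "strong"))
  if (!is.finite(fu_plasma) || fu_plasma <= 0 || fu_plasma > 1)
    stop("fu_plasma must lie in (0, 1], got ", fu_plasma, call. = FALSE)
  if (!is.finite(bp_ratio) || bp_ratio <= 0)
    stop("bp_ratio must be positive, got ", bp_ratio, call. = FALSE)
  if (!is.finite(kd_egfr_nM) || kd_egfr_nM <= 0)
    stop("kd_egfr_nM must be positive, got ", kd_egfr_nM, call. = FALSE)
  if ((base_class == "strong") != (pka > 7))
    stop("base_class '", base_class, "' inconsistent with pka ", pka,
         " (strong iff pka > 7)", call. = FALSE)
  structure(
    list(name = name, log_p = log_p, pka = pka, fu_plasma = fu_plasma,
         bp_ratio = bp_ratio, kd_egfr_nM = kd_egfr_nM,
         base_class = base_class),
    provenance = provenance, class = "compound_params")
}

#' Lysosome-bearing cell population of a tissue
#'
#' @param name Population label.
#' @param fraction Fraction of tissue cells of this type, in \[0, 1\].
#' @param f_lys Fractional lysosomal volume of this cell type, in \[0, 1\].
#' @param ph_lys Lysosomal pH; must be acidic (< 7).
#' @param provenance Named character vector of value sources.
#' @return An object of class `cell_type`.
#' @export
cell_type <- function(name, fraction, f_lys, ph_lys, provenance = character()) {
  if (fraction < 0 || fraction > 1)
    stop("cell-type fraction must lie in [0, 1], got ", fraction, call. = FALSE)
  if (f_lys < 0 || f_lys > 1)
    stop("f_lys must lie in [0, 1], got ", f_lys, call. = FALSE)
  if (ph_lys >= 7)
    stop("ph_lys must be acidic (< 7), got ", ph_lys, call. = FALSE)
  structure(list(name = name, fraction = fraction, f_lys = f_lys,
                 ph_lys = ph_lys),
            provenance = provenance, class = "cell_type")
}

#' Tissue composition for partition modelling
#'
#' Fractional volumes, binding-site concentrations and compartment pH values
#' for one tissue. Tissues with no lysosomal data carry an empty `cell_types`
#' list and contribute no lysosomal term.
#'
#' @param name Tissue label.
#' @param f_nl,f_np,f_ew,f_iw Fractional volumes of neutral lipids, neutral
#'   phospholipids, extracellular water and intracellular water, each in
#'   \[0, 1\] with `f_ew + f_iw <= 1`.
#' @param ap_conc_mg_g Acidic-phospholipid concentration, mg/g.
#' @param alb_ratio Albumin tissue-to-plasma ratio.
#' @param egfr_nM EGFR concentration in nM; 0 where the receptor is absent.
#' @param ph_ew,ph_iw pH of extra-/intracellular water.
#' @param cell_types List of [cell_type()] objects; their fractions must sum
#'   to 1 (within 0.005) when the list is non-empty.
#' @param provenance Named character vector of value sources.
#' @return An object of class `tissue_composition`.
#' @export
tissue_composition <- function(name, f_nl, f_np, f_ew, f_iw, ap_conc_mg_g,
                               alb_ratio, egfr_nM, ph_ew, ph_iw = 7.0,
                               cell_types = list(), provenance = character()) {
  fr <- c(f_nl = f_nl, f_np = f_np, f_ew = f_ew, f_iw = f_iw)
  bad <- fr < 0 | fr > 1
  if (any(bad))
    stop("fractional volumes must lie in [0, 1]; offending: ",
         paste(names(fr)[bad], collapse = ", "), call. = FALSE)
  if (f_ew + f_iw > 1)
    stop("f_ew + f_iw must not exceed 1 (got ", f_ew + f_iw, ")", call. = FALSE)
  if (egfr_nM < 0) stop("egfr_nM must be >= 0", call. = FALSE)
  if (ap_conc_mg_g < 0) stop("ap_conc_mg_g must be >= 0", call. = FALSE)
  if (length(cell_types)) {
    if (!all(vapply(cell_types, inherits, logical(1), "cell_type")))
      stop("cell_types must be a list of cell_type objects", call. = FALSE)
    s <- sum(vapply(cell_types, `[[`, numeric(1), "fraction"))
    if (abs(s - 1) > 0.005)
      stop("cell-type fractions must sum to 1 (got ", s, ")", call. = FALSE)
  }
  structure(
    list(name = name, f_nl = f_nl, f_np = f_np, f_ew = f_ew, f_iw = f_iw,
         ap_conc_mg_g = ap_conc_mg_g, alb_ratio = alb_ratio,
         egfr_nM = egfr_nM, ph_ew = ph_ew, ph_iw = ph_iw,
         cell_types = cell_types),
    provenance = provenance, class = "tissue_composition")
}

#' Blood and blood-cell parameters
#'
#' Haematocrit, plasma and blood-cell pH, and the blood-cell composition used
#' to calibrate the acidic-phospholipid association constant of strong bases.
#'
#' @param hematocrit Volume fraction of blood cells, in (0, 1).
#' @param ph_plasma Plasma pH.
#' @param ph_bc Blood-cell intracellular pH.
#' @param bc_f_iw,bc_f_nl,bc_f_np Blood-cell fractional volumes.
#' @param bc_ap_mg_g Blood-cell acidic-phospholipid concentration, mg/g.
#' @param provenance Named character vector of value sources.
#' @return An object of class `blood_params`.
#' @export
blood_params <- function(hematocrit, ph_plasma, ph_bc, bc_f_iw, bc_f_nl,
                         bc_f_np, bc_ap_mg_g, provenance = character()) {
  if (hematocrit <= 0 || hematocrit >= 1)
    stop("hematocrit must lie in (0, 1)", call. = FALSE)
  fr <- c(bc_f_iw = bc_f_iw, bc_f_nl = bc_f_nl, bc_f_np = bc_f_np)
  if (any(fr < 0 | fr > 1))
    stop("blood-cell fractions must lie in [0, 1]", call. = FALSE)
  structure(
    list(hematocrit = hematocrit, ph_plasma = ph_plasma, ph_bc = ph_bc,
         bc_f_iw = bc_f_iw, bc_f_nl = bc_f_nl, bc_f_np = bc_f_np,
         bc_ap_mg_g = bc_ap_mg_g),
    provenance = provenance, class = "blood_params")
}

tbl3 <- function(what) paste0("tissue/compound parameter table: ", what)

#' Default tracer, tissue and blood parameters
#'
#' Returns the canonical parameter registry: the three tracers (erlotinib, a
#' weak base; afatinib and osimertinib, strong bases), six tissues in the
#' reporting order brain, lung, spleen, kidney, bone, tumor, and the blood
#' parameters used for the acidic-phospholipid calibration.
#'
#' Tumor composition is derived from lung by the NSCLC-hallmark overrides:
#' acidic extracellular water (pH 6.7), a single residual-cell lysosomal
#' population (immune deprivation), elevated EGFR, and lung-inherited
#' acidic-phospholipid and albumin values. Lung and tumor share `f_iw = 0.43`
#' from the main tissue table. Tissues without a cell-type sub-table (brain,
#' spleen, kidney) carry one lysosomal population with the tissue-level
#' lysosomal volume fraction and lysosomal pH 5.3; bone has no lysosomal data
#' and no lysosomal term.
#'
#' @param lung_ph_ew Extracellular-water pH of lung. The default 7.4 is the
#'   physiological value consistent with the published component shares; the
#'   alternative tabulated value 7.22 is selectable.
#' @return An object of class `parameter_set`: a list with elements
#'   `compounds` (named list of [compound_params()]), `tissues` (named list of
#'   [tissue_composition()]) and `blood` ([blood_params()]).
#' @examples
#' p <- default_parameters()
#' p$compounds$osimertinib$pka
#' p$tissues$lung$ap_conc_mg_g
#' @export
default_parameters <- function(lung_ph_ew = 7.4) {
  compounds <- list(
    erlotinib = compound_params(
      "erlotinib", log_p = 3.3, pka = 5.5, fu_plasma = 0.088,
      bp_ratio = 0.95, kd_egfr_nM = 2164,
      provenance = c(log_p = tbl3("Log P 3.3"), pka = tbl3("pKa 5.5"),
                     fu_plasma = tbl3("F_unbound 0.088"),
                     bp_ratio = tbl3("B:P ratio 0.95"),
                     kd_egfr_nM = tbl3("Kd EGFR 2164 nM"))),
    afatinib = compound_params(
      "afatinib", log_p = 3.6, pka = 8.2, fu_plasma = 0.095,
      bp_ratio = 1.27, kd_egfr_nM = 2,
      provenance = c(log_p = tbl3("Log P 3.6"), pka = tbl3("pKa 8.2"),
                     fu_plasma = tbl3("F_unbound 0.095"),
                     bp_ratio = tbl3("B:P ratio 1.27"),
                     kd_egfr_nM = tbl3("Kd EGFR 2 nM"))),
    osimertinib = compound_params(
      "osimertinib", log_p = 3.2, pka = 9.0, fu_plasma = 0.017,
      bp_ratio = 0.79, kd_egfr_nM = 155,
      provenance = c(log_p = tbl3("Log P 3.2"), pka = tbl3("pKa 9.0"),
                     fu_plasma = tbl3("F_unbound 0.017"),
                     bp_ratio = tbl3("B:P ratio 0.79"),
                     kd_egfr_nM = tbl3("Kd EGFR 155 nM"))))

  lung_cells <- list(
    cell_type("alveolar_macrophages", fraction = 0.041, f_lys = 0.078,
              ph_lys = 4.75,
              provenance = c(all = tbl3("lung sub-table, alveolar macrophages"))),
    cell_type("type_ii", fraction = 0.083, f_lys = 0.03, ph_lys = 5.1,
              provenance = c(all = tbl3("lung sub-table, type II cells"))),
    cell_type("residual", fraction = 0.876, f_lys = 0.01, ph_lys = 5.1,
              provenance = c(all = paste0(
                tbl3("lung sub-table, residual cells"),
                "; fraction 0.876 so cell fractions sum to 1 ",
                "(table prints the rounded 0.88)"))))
  # no cell-type sub-table for brain/spleen/kidney: one lysosomal population
  # at the tissue-level F_lys with the footnote lysosomal pH 5.3
  bulk_cells <- function(f_lys) list(
    cell_type("residual", fraction = 1, f_lys = f_lys, ph_lys = 5.3,
              provenance = c(all = tbl3(
                "tissue-row F_lys with footnote lysosomal pH 5.3"))))

  tp <- function(tissue) c(
    f_nl = tbl3(paste(tissue, "F_nl")), f_np = tbl3(paste(tissue, "F_np")),
    f_ew = tbl3(paste(tissue, "F_ew")), f_iw = tbl3(paste(tissue, "F_iw")),
    ap_conc_mg_g = tbl3(paste(tissue, "[AP-]")),
    alb_ratio = tbl3(paste(tissue, "albumin tissue-to-plasma ratio")),
    egfr_nM = tbl3(paste(tissue, "[EGFR]")),
    ph_ew = "physiological extracellular pH 7.4",
    ph_iw = tbl3("footnote pH_iw 7.0"))

  tissues <- list(
    brain = tissue_composition(
      "brain", f_nl = 0.039, f_np = 0.0015, f_ew = 0.16, f_iw = 0.61,
      ap_conc_mg_g = 0.40, alb_ratio = 0.048, egfr_nM = 0, ph_ew = 7.4,
      cell_types = bulk_cells(0.014),
      provenance = `[<-`(tp("brain"), "egfr_nM",
                         "EGFR assumed absent: no literature concentration")),
    lung = tissue_composition(
      "lung", f_nl = 0.0088, f_np = 0.0030, f_ew = 0.34, f_iw = 0.43,
      ap_conc_mg_g = 0.57, alb_ratio = 0.21, egfr_nM = 31.1,
      ph_ew = lung_ph_ew, cell_types = lung_cells,
      provenance = `[<-`(tp("lung"), "ph_ew", paste0(
        "lung pH_ew ", lung_ph_ew,
        " (7.4 physiological default; tabulated 7.22 selectable); ",
        "footnote pH_lys 5.3 superseded by cell-type values here"))),
    spleen = tissue_composition(
      "spleen", f_nl = 0.021, f_np = 0.017, f_ew = 0.21, f_iw = 0.53,
      ap_conc_mg_g = 3.18, alb_ratio = 0.097, egfr_nM = 54.6, ph_ew = 7.4,
      cell_types = bulk_cells(0.053), provenance = tp("spleen")),
    kidney = tissue_composition(
      "kidney", f_nl = 0.039, f_np = 0.012, f_ew = 0.27, f_iw = 0.47,
      ap_conc_mg_g = 2.44, alb_ratio = 0.13, egfr_nM = 177, ph_ew = 7.4,
      cell_types = bulk_cells(0.017), provenance = tp("kidney")),
    bone = tissue_composition(
      "bone", f_nl = 0.017, f_np = 0.0017, f_ew = 0.1, f_iw = 0.35,
      ap_conc_mg_g = 0.67, alb_ratio = 0.10, egfr_nM = 0, ph_ew = 7.4,
      cell_types = list(),
      provenance = `[<-`(tp("bone"), "egfr_nM",
                         "EGFR assumed absent: no literature concentration")),
    tumor = tissue_composition(
      "tumor", f_nl = 0.008, f_np = 0.0030, f_ew = 0.34, f_iw = 0.43,
      ap_conc_mg_g = 0.57, alb_ratio = 0.21, egfr_nM = 299, ph_ew = 6.7,
      cell_types = list(
        cell_type("residual", fraction = 1, f_lys = 0.01, ph_lys = 5.1,
                  provenance = c(all = tbl3("tumor residual cells")))),
      provenance = `[<-`(`[<-`(tp("tumor"), "ap_conc_mg_g",
        "inherited from lung (tumor derived from lung by hallmark overrides)"),
        "alb_ratio",
        "inherited from lung (tumor derived from lung by hallmark overrides)")))

  blood <- blood_params(
    hematocrit = 0.45, ph_plasma = 7.4, ph_bc = 7.22,
    bc_f_iw = 0.60, bc_f_nl = 0.0017, bc_f_np = 0.0029, bc_ap_mg_g = 0.50,
    provenance = c(hematocrit = tbl3("footnote hematocrit 0.45"),
                   ph_plasma = tbl3("footnote pH_p 7.4"),
                   ph_bc = tbl3("footnote 7.22, blood-cell intracellular pH"),
                   bc_f_iw = tbl3("blood cells F_iw 0.60"),
                   bc_f_nl = tbl3("blood cells F_nl 1.7e-3"),
                   bc_f_np = tbl3("blood cells F_np 0.0029"),
                   bc_ap_mg_g = tbl3("blood cells [AP-] 0.50")))

  structure(list(compounds = compounds, tissues = tissues, blood = blood),
            class = "parameter_set")
}

#' PET-image-derived observed tissue-to-blood ratios
#'
#' The built-in validation fixture: observed TBR means and standard deviations
#' from whole-body PET/CT of NSCLC patients for the three tracers across six
#' tissues. The erlotinib scans did not include brain in the field of view, so
#' that record is flagged unavailable.
#'
#' @return A data.frame with columns `compound`, `tissue`, `mean`, `sd`,
#'   `available` (18 rows, 17 available).
#' @export
observed_tbr <- function() {
  df <- rbind(
    data.frame(compound = "erlotinib",
               tissue = c("brain", "lung", "spleen", "kidney", "bone", "tumor"),
               mean = c(NA, 0.51, 1.46, 1.69, 1.23, 1.42),
               sd = c(NA, 0.2, 0.4, 0.6, 0.2, 0.5)),
    data.frame(compound = "afatinib",
               tissue = c("brain", "lung", "spleen", "kidney", "bone", "tumor"),
               mean = c(0.08, 2.54, 13.23, 6.93, 4.81, 3.60),
               sd = c(0.03, 1.2, 2.3, 1.8, 2.0, 2.4)),
    data.frame(compound = "osimertinib",
               tissue = c("brain", "lung", "spleen", "kidney", "bone", "tumor"),
               mean = c(0.79, 7.01, 18.09, 5.61, 4.24, 5.60),
               sd = c(0.5, 1.6, 7.7, 2.0, 0.7, 2.0)))
  df$available <- !is.na(df$mean)
  rownames(df) <- NULL
  df
}

#' Apply user overrides to a parameter set
#'
#' Deep-merges an override document onto a parameter set, re-validating every
#' touched object so out-of-range values are rejected with the constructor's
#' diagnostic. Unknown compounds, tissues or fields are rejected by name.
#'
#' @param params A [parameter_set][default_parameters()].
#' @param overrides Nested list mirroring the parameter-set structure, e.g.
#'   `list(compounds = list(erlotinib = list(fu_plasma = 0.176)))`. Cell types
#'   are overridden as `cell_types = list(residual = list(f_lys = 0.02))`.
#' @return A parameter set with only the named fields changed.
#' @export
apply_overrides <- function(params, overrides) {
  stopifnot(inherits(params, "parameter_set"))
  if (is.null(overrides) || !length(overrides)) return(params)
  ok_top <- c("compounds", "tissues", "blood")
  unknown <- setdiff(names(overrides), ok_top)
  if (length(unknown))
    stop("unknown override section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  patch <- function(obj, ov, what, rebuild) {
    unknown <- setdiff(names(ov), names(obj))
    if (length(unknown))
      stop("unknown field(s) for ", what, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    fields <- unclass(obj)
    prov <- attr(obj, "provenance")
    for (f in names(ov)) {
      fields[[f]] <- ov[[f]]
      if (!is.null(prov) && f %in% names(prov)) prov[f] <- "user override"
    }
    rebuild(fields, prov)
  }
  for (cn in names(overrides$compounds)) {
    if (!cn %in% names(params$compounds))
      stop("unknown compound: ", cn, call. = FALSE)
    params$compounds[[cn]] <- patch(
      params$compounds[[cn]], overrides$compounds[[cn]], paste("compound", cn),
      function(f, prov) compound_params(
        f$name, f$log_p, f$pka, f$fu_plasma, f$bp_ratio, f$kd_egfr_nM,
        f$base_class, provenance = prov))
  }
  for (tn in names(overrides$tissues)) {
    if (!tn %in% names(params$tissues))
      stop("unknown tissue: ", tn, call. = FALSE)
    ov <- overrides$tissues[[tn]]
    tis <- params$tissues[[tn]]
    ct_ov <- ov$cell_types
    ov$cell_types <- NULL
    if (!is.null(ct_ov)) {
      ct_names <- vapply(tis$cell_types, `[[`, character(1), "name")
      for (ctn in names(ct_ov)) {
        i <- match(ctn, ct_names)
        if (is.na(i))
          stop("unknown cell type '", ctn, "' in tissue ", tn, call. = FALSE)
        tis$cell_types[[i]] <- patch(
          tis$cell_types[[i]], ct_ov[[ctn]], paste("cell type", ctn),
          function(f, prov) cell_type(f$name, f$fraction, f$f_lys, f$ph_lys,
                                      provenance = prov))
      }
    }
    params$tissues[[tn]] <- patch(
      tis, ov, paste("tissue", tn),
      function(f, prov) tissue_composition(
        f$name, f$f_nl, f$f_np, f$f_ew, f$f_iw, f$ap_conc_mg_g, f$alb_ratio,
        f$egfr_nM, f$ph_ew, f$ph_iw, f$cell_types, provenance = prov))
  }
  if (!is.null(overrides$blood)) {
    params$blood <- patch(
      params$blood, overrides$blood, "blood",
      function(f, prov) blood_params(
        f$hematocrit, f$ph_plasma, f$ph_bc, f$bc_f_iw, f$bc_f_nl, f$bc_f_np,
        f$bc_ap_mg_g, provenance = prov))
  }
  params
}

strip_for_yaml <- function(x) {
  if (inherits(x, c("compound_params", "tissue_composition", "cell_type",
                    "blood_params"))) {
    lapply(unclass(x), strip_for_yaml)
  } else if (is.list(x)) lapply(x, strip_for_yaml) else x
}

#' Write a parameter set to a YAML file
#'
#' @param params A parameter set.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_parameters()] for the inverse; the round trip is lossless.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "parameter_set"))
  doc <- list(compounds = lapply(params$compounds, strip_for_yaml),
              tissues = lapply(params$tissues, strip_for_yaml),
              blood = strip_for_yaml(params$blood))
  writeLines(yaml::as.yaml(doc, precision = 12L), path)
  invisible(path)
}

#' Read a parameter set from a YAML file
#'
#' Reconstructs and re-validates a full parameter set previously written with
#' [write_parameters()] (or hand-edited in the same layout).
#'
#' @param path YAML file path.
#' @return A `parameter_set`.
#' @export
read_parameters <- function(path) {
  doc <- yaml::read_yaml(path)
  for (sec in c("compounds", "tissues", "blood"))
    if (is.null(doc[[sec]])) stop("parameter file lacks '", sec, "' section",
                                  call. = FALSE)
  compounds <- lapply(doc$compounds, function(f) compound_params(
    f$name, f$log_p, f$pka, f$fu_plasma, f$bp_ratio, f$kd_egfr_nM,
    f$base_class, provenance = c(all = paste("loaded from", path))))
  tissues <- lapply(doc$tissues, function(f) {
    cts <- lapply(f$cell_types, function(ct) cell_type(
      ct$name, ct$fraction, ct$f_lys, ct$ph_lys,
      provenance = c(all = paste("loaded from", path))))
    tissue_composition(
      f$name, f$f_nl, f$f_np, f$f_ew, f$f_iw, f$ap_conc_mg_g, f$alb_ratio,
      f$egfr_nM, f$ph_ew, f$ph_iw, cts,
      provenance = c(all = paste("loaded from", path)))
  })
  b <- doc$blood
  blood <- blood_params(b$hematocrit, b$ph_plasma, b$ph_bc, b$bc_f_iw,
                        b$bc_f_nl, b$bc_f_np, b$bc_ap_mg_g,
                        provenance = c(all = paste("loaded from", path)))
  structure(list(compounds = compounds, tissues = tissues, blood = blood),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("PBPK parameter set:", length(x$compounds), "compounds,",
      length(x$tissues), "tissues\n")
  cat(" compounds:", paste(names(x$compounds), collapse = ", "), "\n")
  cat(" tissues:  ", paste(names(x$tissues), collapse = ", "), "\n")
  invisible(x)
}
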