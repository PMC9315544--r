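#' Fraction of a base that is protonated at a given pH
#'
#' Henderson-Hasselbalch ionization for a monoprotic base:
#' `1 / (1 + 10^(pH - pKa))`. A weak base (pKa 5.5) is therefore ~1%
#' protonated at plasma pH 7.4, while strong bases (pKa 8.2, 9.0) are mostly
#' protonated.
#'
#' @param pka Basicity constant.
#' @param ph Ambient pH.
#' @param orientation `"base"` (default) is the Henderson-Hasselbalch
#'   orientation above. `"as_printed"` evaluates `1 / (1 + 10^(pKa - pH))`,
#'   the transcription found in some reports of this model family; it is the
#'   complement of the correct value and is retained only for forensic
#'   comparison.
#' @return Fraction in (0, 1); vectorized over `pka` and `ph`.
#' @examples
#' fraction_protonated(5.5, 7.4)  # ~0.0124: a weak base, 99% unprotonated
#' fraction_protonated(9.0, 7.4)  # ~0.98: a strong base
#' @export
fraction_protonated <- function(pka, ph, orientation = c("base", "as_printed")) {
  orientation <- match.arg(orientation)
  if (orientation == "base") 1 / (1 + 10^(ph - pka)) else 1 / (1 + 10^(pka - ph))
}

#' Ionization ratio between two pH environments
#'
#' The factor `(1 + 10^(pKa - ph_num)) / (1 + 10^(pKa - ph_den))` by which
#' total (protonated + neutral) drug accumulates in a compartment at `ph_num`
#' relative to one at `ph_den`, assuming only the neutral species
#' equilibrates across the membrane. Equals 1 when the two pH values agree,
#' and satisfies `ionization_factor(pka, a, b) * ionization_factor(pka, b, a)
#' == 1`.
#'
#' @param pka Basicity constant.
#' @param ph_num pH of the accumulating compartment.
#' @param ph_den pH of the reference compartment.
#' @return Strictly positive factor; vectorized.
#' @export
ionization_factor <- function(pka, ph_num, ph_den) {
  (1 + 10^(pka - ph_num)) / (1 + 10^(pka - ph_den))
}

#' Scaled albumin binding capacity from plasma protein binding
#'
#' Attributes all plasma binding of a weak base to albumin, so the product of
#' the albumin association constant and the plasma albumin concentration is
#' fixed by the fraction unbound alone: `bound/unbound = 1/fu - 1`. Scaling
#' by the albumin tissue-to-plasma ratio then gives the tissue albumin term.
#'
#' @param fu_plasma Fraction unbound in plasma, in (0, 1].
#' @return Unitless binding capacity `1/fu - 1` (>= 0).
#' @export
albumin_binding_capacity <- function(fu_plasma) {
  if (any(!is.finite(fu_plasma)) || any(fu_plasma <= 0) || any(fu_plasma > 1))
    stop("fu_plasma must lie in (0, 1]", call. = FALSE)
  1 / fu_plasma - 1
}

#' Unbound blood-cell to plasma partition coefficient
#'
#' Solves the whole-blood mass balance `B:P = (1 - H) + H * Kpu_bc * fu` for
#' the unbound blood-cell partition coefficient. Requires `bp_ratio` above
#' the plasma fraction `1 - H`; a smaller value would imply a negative drug
#' concentration in blood cells.
#'
#' @param bp_ratio Whole-blood to plasma concentration ratio. Must not fall
#'   below the plasma volume fraction `1 - hematocrit`; equality means no
#'   cellular uptake and returns 0.
#' @param hematocrit Blood-cell volume fraction, in (0, 1).
#' @param fu_plasma Fraction unbound in plasma.
#' @return `(bp_ratio - (1 - hematocrit)) / (hematocrit * fu_plasma)`.
#' @export
blood_cell_partition <- function(bp_ratio, hematocrit, fu_plasma) {
  if (any(bp_ratio < 1 - hematocrit))
    stop("bp_ratio (", paste(bp_ratio, collapse = ", "),
         ") must be at least the plasma fraction 1 - hematocrit (",
         1 - hematocrit, "): implied blood-cell concentration is negative",
         call. = FALSE)
  (bp_ratio - (1 - hematocrit)) / (hematocrit * fu_plasma)
}

#' Lipophilicity value used in the lipid-binding terms
#'
#' @param log_p Octanol/water log-partition value.
#' @param convention `"direct"` (default) uses the log P number itself as the
#'   lipid affinity `P`, the convention of the published model this package
#'   reconstructs; `"power"` uses the thermodynamic partition coefficient
#'   `10^log_p`.
#' @return Numeric affinity value.
#' @export
lipophilicity_value <- function(log_p, convention = c("direct", "power")) {
  convention <- match.arg(convention)
  if (convention == "direct") log_p else 10^log_p
}

# neutral-lipid / neutral-phospholipid affinity numerator, shared by the
# tissue term and the blood-cell calibration
nl_np_numerator <- function(p, f_nl, f_np) p * f_nl + (0.3 * p + 0.7) * f_np

#' Acidic-phospholipid association constant calibrated from blood cells
#'
#' For strong bases, the association constant Ka for the protonated species
#' binding to acidic phospholipids (AP-) is calibrated from blood-cell
#' partitioning: the unbound blood-cell coefficient
#' ([blood_cell_partition()]) is decomposed into an intracellular-water term,
#' a neutral-lipid term and the AP- term, and the AP- term is solved for Ka:
#'
#' `Ka = (Kpu_bc - IF(pKa, pH_bc, pH_p) * f_iw,bc -
#'        (P*f_nl,bc + (0.3P+0.7)*f_np,bc) / (1 + 10^(pKa - pH_p)))
#'       * (1 + 10^(pKa - pH_p)) / ([AP-]_bc * 10^(pKa - pH_bc))`
#'
#' @param compound A [compound_params()] object with `base_class = "strong"`.
#' @param blood A [blood_params()] object.
#' @param logp_convention Passed to [lipophilicity_value()].
#' @return Association constant per (mg/g) of acidic phospholipid (> 0).
#' @export
ap_association_constant <- function(compound, blood,
                                    logp_convention = c("direct", "power")) {
  stopifnot(inherits(compound, "compound_params"),
            inherits(blood, "blood_params"))
  if (compound$base_class != "strong")
    stop("acidic-phospholipid calibration applies to strong bases only; '",
         compound$name, "' is a ", compound$base_class, " base", call. = FALSE)
  p <- lipophilicity_value(compound$log_p, logp_convention)
  kpu_bc <- blood_cell_partition(compound$bp_ratio, blood$hematocrit,
                                 compound$fu_plasma)
  iw_term <- ionization_factor(compound$pka, blood$ph_bc, blood$ph_plasma) *
    blood$bc_f_iw
  nl_term <- nl_np_numerator(p, blood$bc_f_nl, blood$bc_f_np) /
    (1 + 10^(compound$pka - blood$ph_plasma))
  remainder <- kpu_bc - iw_term - nl_term
  # tolerate rounding noise at an exactly-zero AP- remainder
  if (remainder < -1e-9 * max(kpu_bc, 1))
    stop("blood-cell partitioning of ", compound$name,
         " is over-explained without acidic phospholipids ",
         "(negative AP- remainder ", signif(remainder, 4), ")", call. = FALSE)
  remainder <- max(remainder, 0)
  remainder * (1 + 10^(compound$pka - blood$ph_plasma)) /
    (blood$bc_ap_mg_g * 10^(compound$pka - blood$ph_bc))
}
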