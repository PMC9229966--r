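# Compound-level constants and tissue partitioning.

MODEL_TISSUES <- c("adipose", "bone", "brain", "gut", "heart", "kidney",
                   "liver", "lung", "muscle", "skin", "spleen", "pancreas",
                   "rest")

.pkg_cache <- new.env(parent = emptyenv())

#' Renal transporter parameter set
#'
#' Per-cell intrinsic clearances of the renal proximal-tubule transporters
#' handling an organic-anion cephalosporin: basolateral uptake (OAT1, OAT3),
#' apical efflux (MRP4) and passive bidirectional diffusion, plus kidney-cell
#' and urine unbound fractions. Absent transporters are represented as 0.
#'
#' @param clint_oat1_uptake,clint_oat3_uptake basolateral uptake intrinsic
#'   clearance, uL/min/1e6 cells.
#' @param clint_mrp4_efflux apical efflux intrinsic clearance, uL/min/1e6
#'   cells.
#' @param clpd_basal,clpd_apical passive diffusion clearance across the
#'   basolateral / apical membrane, mL/min/1e6 cells.
#' @param fu_kidney_cell,fu_urine unbound fractions in kidney cell water and
#'   urine, in (0, 1].
#' @return An object of class `renal_transporter_set`.
#' @export
renal_transporter_set <- function(clint_oat1_uptake = 0,
                                  clint_oat3_uptake = 0,
                                  clint_mrp4_efflux = 0,
                                  clpd_basal = 0,
                                  clpd_apical = 0,
                                  fu_kidney_cell = 1,
                                  fu_urine = 1) {
  vals <- c(clint_oat1_uptake, clint_oat3_uptake, clint_mrp4_efflux,
            clpd_basal, clpd_apical)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("transporter clearances must be finite and >= 0")
  if (fu_kidney_cell <= 0 || fu_kidney_cell > 1 ||
      fu_urine <= 0 || fu_urine > 1)
    stop("fu_kidney_cell and fu_urine must be in (0, 1]")
  structure(list(clint_oat1_uptake = clint_oat1_uptake,
                 clint_oat3_uptake = clint_oat3_uptake,
                 clint_mrp4_efflux = clint_mrp4_efflux,
                 clpd_basal = clpd_basal,
                 clpd_apical = clpd_apical,
                 fu_kidney_cell = fu_kidney_cell,
                 fu_urine = fu_urine),
            class = "renal_transporter_set")
}

#' Compound parameter set
#'
#' Physicochemical and kinetic constants describing one drug in the
#' whole-body model: ionization (monoprotic acid), blood/plasma ratio,
#' plasma unbound fraction, tissue partitioning (global Kp scalar plus
#' tissue-specific overrides), the adipose transmembrane passive diffusion
#' clearance CLPD, and the renal transporter set.
#'
#' @param name compound name.
#' @param molecular_weight g/mol.
#' @param log_p octanol-water log partition coefficient.
#' @param acid_pka acid dissociation constant.
#' @param compound_type only `"monoprotic_acid"` is modelled.
#' @param blood_to_plasma blood-to-plasma concentration ratio (B/P), > 0.
#' @param fu_plasma fraction unbound in plasma, in (0, 1].
#' @param kp_scalar global multiplier applied to predicted Kp values.
#' @param kp_overrides named list of tissue Kp values that replace the
#'   prediction (override precedence is total).
#' @param adipose_clpd passive diffusion clearance between adipose ISF and
#'   intracellular water, L/h.
#' @param renal a [renal_transporter_set()].
#' @return An object of class `compound_params`.
#' @seealso [load_compound()] for the packaged cefazolin/cefuroxime files.
#' @export
compound_params <- function(name, molecular_weight, log_p, acid_pka,
                            compound_type = "monoprotic_acid",
                            blood_to_plasma, fu_plasma, kp_scalar = 1,
                            kp_overrides = list(), adipose_clpd = 0.1,
                            renal = renal_transporter_set()) {
  compound_type <- match.arg(compound_type, "monoprotic_acid")
  if (!is.finite(fu_plasma) || fu_plasma <= 0 || fu_plasma > 1)
    stop("fu_plasma must be in (0, 1]")
  if (!is.finite(blood_to_plasma) || blood_to_plasma <= 0)
    stop("blood_to_plasma must be > 0")
  if (adipose_clpd < 0) stop("adipose_clpd must be >= 0")
  kp_overrides <- lapply(kp_overrides, as.numeric)
  if (length(kp_overrides) && any(unlist(kp_overrides) < 0))
    stop("Kp overrides must be >= 0")
  if (!inherits(renal, "renal_transporter_set"))
    renal <- do.call(renal_transporter_set, renal)
  structure(list(name = name,
                 molecular_weight = molecular_weight,
                 log_p = log_p,
                 acid_pka = acid_pka,
                 compound_type = compound_type,
                 blood_to_plasma = blood_to_plasma,
                 fu_plasma = fu_plasma,
                 kp_scalar = kp_scalar,
                 kp_overrides = kp_overrides,
                 adipose_clpd = adipose_clpd,
                 renal = renal),
            class = "compound_params")
}

#' Load a packaged (or user) compound file
#'
#' Compound files are YAML key-value files mirroring the
#' [compound_params()] fields; `"cefazolin"` and `"cefuroxime"` ship with
#' the package.
#'
#' @param name compound name (packaged file) or a path to a YAML file.
#' @return A `compound_params` object.
#' @export
load_compound <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0(name, ".yaml"), package = "cephpbpk")
  if (!nzchar(path) || !file.exists(path))
    stop("no compound file for '", name, "'")
  spec <- yaml::read_yaml(path)
  spec$renal <- do.call(renal_transporter_set, spec$renal)
  do.call(compound_params, spec)
}

#' Tissue composition table
#'
#' Fractional extracellular/intracellular water, neutral lipid, neutral
#' phospholipid, tissue-to-plasma albumin ratio and intracellular pH for
#' every modelled tissue plus a plasma row. Used by the Rodgers-Rowland
#' partition prediction and the intracellular unbound-fraction equation.
#'
#' @return A data.frame with one row per tissue.
#' @export
tissue_composition <- function() {
  if (is.null(.pkg_cache$composition)) {
    path <- system.file("extdata", "tissue_composition.csv",
                        package = "cephpbpk")
    .pkg_cache$composition <- utils::read.csv(path, comment.char = "#")
  }
  .pkg_cache$composition
}

.composition_row <- function(composition, tissue) {
  row <- composition[composition$tissue == tissue, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("no composition entry for tissue '", tissue, "'")
  row
}

#' Ionized fraction of a monoprotic acid (Henderson-Hasselbalch)
#'
#' For an acid the ionized fraction is `1 - 1/(1 + 10^(ph - pka))`,
#' equivalently the complement of the neutral fraction `1/(1 + 10^(ph-pka))`.
#'
#' @param pka acid dissociation constant.
#' @param ph medium pH.
#' @return Fraction ionized, in (0, 1).
#' @export
ionized_fraction <- function(pka, ph) {
  stopifnot(is.finite(pka), is.finite(ph))
  1 - 1 / (1 + 10^(ph - pka))
}

# Ratio of total to neutral species for an acid at a given pH:
# X = 1 + 10^(ph - pka).
.acid_x <- function(pka, ph) 1 + 10^(ph - pka)

#' Predict tissue-to-plasma partition coefficients (Rodgers-Rowland)
#'
#' Mechanistic Kp prediction for a monoprotic acid: partitioning into tissue
#' water (with Henderson-Hasselbalch correction between plasma pH 7.4 and
#' intracellular pH), into neutral lipid and phospholipid (neutral species
#' only), and binding to extracellular (albumin-class) protein estimated
#' from the plasma unbound fraction. The unbound-referenced prediction
#' `Kpu` is converted to the total ratio via `Kp = fu * Kpu`, scaled by the
#' compound's global `kp_scalar`, and finally replaced by any tissue listed
#' in `kp_overrides`.
#'
#' @param compound a [compound_params()] object.
#' @param composition a [tissue_composition()] data.frame.
#' @return Named numeric vector of Kp values over the modelled tissues.
#' @export
predict_kp_set <- function(compound, composition = tissue_composition()) {
  stopifnot(inherits(compound, "compound_params"))
  plasma <- .composition_row(composition, "plasma")
  p <- 10^compound$log_p
  fu <- compound$fu_plasma
  y <- .acid_x(compound$acid_pka, 7.4)          # plasma total/neutral ratio
  lipid_p <- (p * plasma$f_nl + (0.3 * p + 0.7) * plasma$f_np) / y
  # Albumin association constant x plasma albumin, from the plasma binding
  # mass balance: 1/fu = 1 + lipid_p + Ka*[PR]p.
  ka_pr <- max(0, 1 / fu - 1 - lipid_p)
  kps <- vapply(MODEL_TISSUES, function(tis) {
    row <- .composition_row(composition, tis)
    x <- .acid_x(compound$acid_pka, row$ph_ic)  # intracellular ratio
    lipid_t <- (p * row$f_nl + (0.3 * p + 0.7) * row$f_np) / y
    kpu <- row$f_water_ec + (x / y) * row$f_water_ic + lipid_t +
      ka_pr * row$albumin_ratio
    fu * kpu * compound$kp_scalar
  }, numeric(1))
  for (tis in names(compound$kp_overrides))
    kps[[tis]] <- compound$kp_overrides[[tis]]
  kps
}

#' Steady-state volume of distribution from a Kp set
#'
#' `Vss = (V_plasma + V_erythrocyte * E:P + sum_t Kp_t * V_t) / body weight`
#' with the erythrocyte-to-plasma ratio derived from B/P and hematocrit:
#' `E:P = (B/P - (1 - Hct)) / Hct`, floored at 0 when the blood/plasma ratio
#' indicates erythrocyte exclusion.
#'
#' @param kps named Kp vector (see [predict_kp_set()]).
#' @param volumes named tissue volume vector, L, covering the same tissues.
#' @param plasma_volume plasma volume, L.
#' @param blood_to_plasma B/P ratio.
#' @param hematocrit fraction in (0, 1).
#' @param body_weight kg.
#' @return Vss in L/kg.
#' @export
compute_vss <- function(kps, volumes, plasma_volume, blood_to_plasma,
                        hematocrit, body_weight) {
  if (hematocrit <= 0 || hematocrit >= 1)
    stop("hematocrit must be in (0, 1)")
  if (any(volumes < 0) || plasma_volume < 0) stop("negative volume")
  common <- intersect(names(kps), names(volumes))
  if (!setequal(names(kps), names(volumes)))
    warning("Kp and volume tissue sets differ; using their intersection")
  ep <- max(0, (blood_to_plasma - (1 - hematocrit)) / hematocrit)
  v_ery <- plasma_volume * hematocrit / (1 - hematocrit)
  (plasma_volume + v_ery * ep +
     sum(kps[common] * volumes[common])) / body_weight
}

#' Intracellular unbound fraction
#'
#' Composition-based prediction of the fraction unbound in tissue cell
#' water, `fuIW`. Binding is to neutral lipid and phospholipid; only the
#' neutral species (fraction `1/X` at intracellular pH, Henderson-
#' Hasselbalch, pH 7.0 by default in the composition table) partitions, so
#'
#' `fuIW = 1 / (1 + (P*f_nl + (0.3P + 0.7)*f_np) / (f_water_ic * X))`
#'
#' with `P = 10^logP` and `X = 1 + 10^(ph_ic - pKa)`. The extracellular
#' unbound fraction `fuISF` is not computed here: it is taken equal to the
#' plasma fu by assumption.
#'
#' @param compound a [compound_params()] object.
#' @param tissue tissue identifier.
#' @param composition a [tissue_composition()] data.frame.
#' @return fuIW in (0, 1].
#' @export
fu_intracellular <- function(compound, tissue,
                             composition = tissue_composition()) {
  row <- .composition_row(composition, tissue)
  if (row$f_water_ic <= 0)
    stop("tissue '", tissue, "' has no intracellular water")
  p <- 10^compound$log_p
  x <- .acid_x(compound$acid_pka, row$ph_ic)
  bound <- (p * row$f_nl + (0.3 * p + 0.7) * row$f_np) /
    (row$f_water_ic * x)
  1 / (1 + bound)
}

#' Predicted Vss for a compound on the reference adult
#'
#' Convenience wrapper: builds the deterministic reference subject (lean,
#' female, variability disabled), predicts the Kp set and folds it into
#' [compute_vss()].
#'
#' @param compound a [compound_params()] object or compound name.
#' @param weight reference body weight, kg.
#' @return Vss in L/kg.
#' @export
vss_reference <- function(compound, weight = 62.3) {
  if (is.character(compound)) compound <- load_compound(compound)
  spec <- population_spec(population_class = "lean", n_subjects = 1,
                          proportion_female = 1,
                          target_mean_weight = weight,
                          variability = FALSE, seed = 1)
  subj <- build_baseline(spec)[[1]]
  kps <- predict_kp_set(compound)
  compute_vss(kps, subj$tissue_volumes, subj$plasma_volume,
              compound$blood_to_plasma, subj$hematocrit, subj$weight)
}
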