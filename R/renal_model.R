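# Renal elimination: glomerular filtration plus transporter-mediated
# tubular secretion scaled from per-cell intrinsic clearances.

#' Kidney scaling constants
#'
#' Scaling from per-cell transporter intrinsic clearances to the whole
#' organ: proximal-tubule cellularity, kidney mass, and renal blood flow.
#'
#' @param cells_per_g proximal tubule cells per gram kidney.
#' @param kidney_mass_g total kidney mass, g.
#' @param q_kidney renal blood flow, L/h.
#' @return An object of class `kidney_scaling`.
#' @export
kidney_scaling <- function(cells_per_g = 60e6, kidney_mass_g = 300,
                           q_kidney = 60) {
  if (cells_per_g <= 0 || kidney_mass_g <= 0 || q_kidney <= 0)
    stop("kidney scaling constants must be > 0")
  structure(list(cells_per_g = cells_per_g, kidney_mass_g = kidney_mass_g,
                 q_kidney = q_kidney), class = "kidney_scaling")
}

#' Gestational OAT3 activity fold change
#'
#' Cubic gestational-age polynomial for renal OAT3 transport activity:
#' `1 * (1 + 0.195*GA - 0.0093*GA^2 + 0.0001154*GA^3)`. Equals 1 at GA 0,
#' about 2.2 at the end of the first trimester and about 1.3 at term.
#'
#' @param ga gestational age, weeks (>= 0).
#' @return Fold change (unitless).
#' @export
oat3_pregnancy_fold <- function(ga) {
  stopifnot(all(ga >= 0))
  1 * (1 + 0.195 * ga - 0.0093 * ga^2 + 0.0001154 * ga^3)
}

#' Transporter-mediated tubular secretion clearance
#'
#' Scales the basolateral uptake intrinsic clearances (OAT1 plus
#' gestationally scaled OAT3) to a whole-organ intrinsic clearance
#' (`uL/min/1e6 cells * cells/g * kidney mass`, unit-converted to L/h) and
#' folds it into a whole-kidney well-stirred model:
#' `CL_sec = Q_k * fu * CLint / (Q_k + fu * CLint)`.
#'
#' Apical efflux (MRP4) is treated as non-rate-limiting while its intrinsic
#' clearance is at least as large as the uptake clearance (back-flux across
#' the basolateral membrane is passive and negligibly small for these
#' compounds); when efflux is smaller than uptake, secretion is scaled by
#' the efflux competition factor
#' `clint_efflux / (clint_efflux + clpd_basal)`.
#'
#' @param compound a [compound_params()] object.
#' @param scaling a [kidney_scaling()] object.
#' @param fu plasma fraction unbound driving the kidney.
#' @param ga gestational age, weeks (applies to the OAT3 component only).
#' @return Secretion clearance, L/h.
#' @export
secretion_clearance <- function(compound, scaling = kidney_scaling(),
                                fu = compound$fu_plasma, ga = 0) {
  stopifnot(inherits(compound, "compound_params"),
            inherits(scaling, "kidney_scaling"))
  renal <- compound$renal
  clint_up <- renal$clint_oat1_uptake +
    oat3_pregnancy_fold(ga) * renal$clint_oat3_uptake
  if (clint_up <= 0) return(0)
  # uL/min/1e6 cells -> L/h for the whole organ
  cells_millions <- scaling$cells_per_g * scaling$kidney_mass_g / 1e6
  clint_organ <- clint_up * cells_millions * 60 / 1e6
  eff <- renal$clint_mrp4_efflux
  if (eff > 0 && eff < clint_up) {
    basal_return <- renal$clpd_basal * 1000  # mL -> uL per min per 1e6 cells
    clint_organ <- clint_organ * eff / (eff + basal_return)
  }
  qk <- scaling$q_kidney
  qk * fu * clint_organ / (qk + fu * clint_organ)
}

#' Total renal clearance for a subject
#'
#' `CL_R = fu * GFR + CL_secretion`; with unit urine unbound fraction there
#' is no reabsorption term, and renal elimination is the only clearance
#' route for these compounds.
#'
#' @param subject a `subject_physiology`.
#' @param compound a [compound_params()] object.
#' @param scaling optional [kidney_scaling()]; defaults to standard
#'   cellularity/mass with the subject's kidney blood flow.
#' @return Renal clearance, L/h.
#' @export
renal_clearance_total <- function(subject, compound, scaling = NULL) {
  stopifnot(inherits(subject, "subject_physiology"))
  if (is.null(scaling))
    scaling <- kidney_scaling(q_kidney = subject$tissue_flows[["kidney"]])
  fu <- compound$fu_plasma
  fu * subject$gfr +
    secretion_clearance(compound, scaling, fu = fu,
                        ga = subject$gestational_age)
}
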