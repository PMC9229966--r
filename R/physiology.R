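# Virtual-subject physiology: demographics, tissue volumes and flows, GFR,
# obesity classes and gestational scaling.

# Reference organ volumes (L) for a BMI-22 adult at reference height
# (female 163 cm / male 176 cm). Adipose is the mass-closure residual.
.REF_ORGANS_F <- c(bone = 7.8, brain = 1.30, gut = 1.10, heart = 0.30,
                   kidney = 0.30, liver = 1.60, lung = 0.50, muscle = 20.0,
                   skin = 2.60, spleen = 0.15, pancreas = 0.12, rest = 2.00)
.REF_ORGANS_M <- c(bone = 10.0, brain = 1.45, gut = 1.20, heart = 0.35,
                   kidney = 0.33, liver = 1.80, lung = 0.60, muscle = 28.0,
                   skin = 3.00, spleen = 0.18, pancreas = 0.14, rest = 2.40)
.REF_BLOOD <- c(female = 4.2, male = 5.3)
.REF_HEIGHT <- c(female = 163, male = 176)
.HEIGHT_SD <- c(female = 6, male = 7)
.HCT <- c(female = 0.40, male = 0.45)
# Baseline creatinine medians are calibrated so the MDRD estimate returns
# the reference healthy young-adult absolute GFR (~120 mL/min female,
# ~140 mL/min male): MDRD systematically underestimates measured GFR in
# healthy adults when fed population-typical creatinine values.
.SCR_MEDIAN <- c(female = 0.55, male = 0.70)

# Relative flow weights (fraction of non-adipose cardiac output); lung is in
# series with the full cardiac output and carries no systemic share.
.FLOW_WEIGHTS <- c(bone = 0.05, brain = 0.12, gut = 0.16, heart = 0.045,
                   kidney = 0.19, liver = 0.07, muscle = 0.18, skin = 0.06,
                   spleen = 0.02, pancreas = 0.01, rest = 0.095)

# Adipose perfusion (L/h per L tissue); obesity lowers per-volume perfusion.
.ADIPOSE_PERFUSION <- c(lean = 0.85, obese = 0.55, morbidly_obese = 0.42)

# Default mean body weights (kg) per class when no study target is given.
.DEFAULT_WEIGHT <- list(
  lean = c(female = 63, male = 78),
  obese = c(female = 95, male = 105),
  morbidly_obese = c(female = 125, male = 135))

# Gestational weight-gain model: total maternal gain at term (39.5 weeks) by
# pre-pregnancy class; the non-adipose part (fetus, placenta, amniotic
# fluid, uterus, breast, plasma, extracellular fluid) is common, the
# adipose gain is the class-specific residual that reproduces the term
# weight anchors (obese 80 -> 97.8 kg, morbidly obese 105 -> 128 kg).
.GAIN_TOTAL <- c(lean = 12.5, obese = 17.8, morbidly_obese = 23)
.GAIN_FETOPLACENTAL <- 4.95   # fetus + placenta + amniotic fluid, kg at term
.GAIN_MATERNAL_SOFT <- 2.87   # uterus + breast + extracellular fluid, kg
.GAIN_PLASMA <- 1.25          # plasma expansion share of the 9.07 kg lump
.GAIN_NONADIPOSE <- .GAIN_FETOPLACENTAL + .GAIN_MATERNAL_SOFT + .GAIN_PLASMA

.gain_shape <- function(ga) (pmax(ga, 0) / 39.5)^1.8

#' Gestational scaling folds
#'
#' Smooth gestational-age polynomials for cardiac output, GFR and plasma
#' volume, anchored to standard pregnancy physiology: cardiac output peaks
#' around +35% in the early third trimester, GFR is about +45% at term,
#' plasma volume about +45% at term. All folds are 1 at GA 0.
#'
#' @param ga gestational age, weeks.
#' @return List with elements `cardiac_output`, `gfr`, `plasma_volume`.
#' @export
pregnancy_folds <- function(ga) {
  stopifnot(ga >= 0)
  list(cardiac_output = 1 + 0.028 * ga - 0.0005 * ga^2,
       gfr = 1 + 0.045 * ga - 0.00085 * ga^2,
       plasma_volume = 1 + 0.00028 * ga^2)
}

#' Population specification
#'
#' Defines one virtual population: obesity class, pregnancy status and
#' gestational age, size, sex mix, age range and weight targeting. When a
#' pregnant population has a `target_mean_weight` (weight *at* the stated
#' GA), the pre-pregnancy baseline weight is derived by subtracting the
#' gestational gain; alternatively give `pre_pregnancy_weight` directly.
#'
#' @param population_class `"lean"`, `"obese"` or `"morbidly_obese"`.
#' @param pregnant logical.
#' @param gestational_age weeks; required > 0 when pregnant.
#' @param n_subjects subjects per trial.
#' @param proportion_female fraction female; must be 1 when pregnant.
#' @param age_range two-element numeric, years.
#' @param target_mean_weight mean body weight target, kg (at GA if
#'   pregnant); the sampled mean is recentred exactly to it.
#' @param pre_pregnancy_weight explicit pre-pregnancy mean weight, kg.
#' @param variability logical; `FALSE` collapses all between-subject
#'   variability (reference individuals).
#' @param seed integer RNG seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(population_class = c("lean", "obese",
                                                 "morbidly_obese"),
                            pregnant = FALSE, gestational_age = 0,
                            n_subjects = 10, proportion_female = 1,
                            age_range = c(20, 40),
                            target_mean_weight = NULL,
                            pre_pregnancy_weight = NULL,
                            variability = TRUE, seed = 1L) {
  population_class <- match.arg(population_class)
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (pregnant) {
    if (gestational_age <= 0 || gestational_age > 42)
      stop("pregnant populations need gestational_age in (0, 42]")
    if (proportion_female != 1)
      stop("pregnant populations must be all female")
  }
  if (proportion_female < 0 || proportion_female > 1)
    stop("proportion_female must be in [0, 1]")
  structure(list(population_class = population_class, pregnant = pregnant,
                 gestational_age = if (pregnant) gestational_age else 0,
                 n_subjects = as.integer(n_subjects),
                 proportion_female = proportion_female,
                 age_range = age_range,
                 target_mean_weight = target_mean_weight,
                 pre_pregnancy_weight = pre_pregnancy_weight,
                 variability = isTRUE(variability),
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Body surface area (DuBois)
#'
#' @param weight kg.
#' @param height cm.
#' @return BSA in m^2.
#' @export
body_surface_area <- function(weight, height) {
  0.007184 * weight^0.425 * height^0.725
}

#' MDRD estimated GFR, normalised
#'
#' `175 * Scr^-1.154 * age^-0.203 * (0.742 if female)`, in mL/min/1.73 m^2.
#'
#' @param age years (>= 18).
#' @param sex `"female"` or `"male"`.
#' @param serum_creatinine mg/dL, > 0.
#' @return eGFR in mL/min/1.73 m^2.
#' @export
mdrd_egfr <- function(age, sex, serum_creatinine) {
  if (serum_creatinine <= 0) stop("serum creatinine must be > 0")
  sex <- match.arg(sex, c("female", "male"))
  175 * serum_creatinine^-1.154 * age^-0.203 *
    (if (sex == "female") 0.742 else 1)
}

#' Absolute MDRD GFR
#'
#' Converts the normalised MDRD estimate to an absolute filtration rate for
#' the subject's body surface area: `eGFR * (BSA / 1.73) * 0.06` L/h.
#'
#' @inheritParams mdrd_egfr
#' @param body_surface_area m^2.
#' @return GFR in L/h.
#' @export
mdrd_gfr <- function(age, sex, serum_creatinine, body_surface_area) {
  mdrd_egfr(age, sex, serum_creatinine) * (body_surface_area / 1.73) * 0.06
}

#' Adipose water sub-compartment geometry
#'
#' The interstitial (ISF) and intracellular (IW) water pools of adipose
#' tissue are fixed fractions of the tissue volume: 14.1% and 3.9%.
#'
#' @param v_adipose adipose tissue volume, L.
#' @return List with `v_adipose`, `v_isf`, `v_iw`, `f_isf`, `f_iw`.
#' @export
adipose_water_partition <- function(v_adipose) {
  if (v_adipose <= 0) stop("adipose volume must be > 0")
  list(v_adipose = v_adipose,
       v_isf = 0.141 * v_adipose,
       v_iw = 0.039 * v_adipose,
       f_isf = 0.141, f_iw = 0.039)
}

# Truncated lognormal multiplier with unit median.
.ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  z <- pmin(pmax(stats::rnorm(n), -3), 3)
  exp(sdlog * z)
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# One non-pregnant subject from already-sampled demographics.
.assemble_subject <- function(class, sex, age, weight, height, scr,
                              co_mult, gfr_mult, organ_mult, flow_mult) {
  ref_organs <- if (sex == "female") .REF_ORGANS_F else .REF_ORGANS_M
  href <- .REF_HEIGHT[[sex]]
  lean_scale <- (height / href)^2           # BMI-22 weight scales with h^2
  w_ref <- 22 * (height / 100)^2
  organs <- ref_organs * lean_scale * organ_mult
  blood <- .REF_BLOOD[[sex]] * lean_scale
  dw <- weight - w_ref
  organs[["muscle"]] <- max(organs[["muscle"]] + 0.20 * dw, 1)
  organs[["skin"]] <- max(organs[["skin"]] + 0.03 * dw, 0.5)
  blood <- max(blood + 0.02 * dw, 2)
  v_adipose <- weight - sum(organs) - blood
  min_adipose <- 0.05 * weight
  if (v_adipose < min_adipose) {
    # Light-for-height subjects carry less lean mass: shrink the lean
    # tissue set proportionally to keep mass closure, floor adipose at 5%
    # of body weight, and only reject targets that stay unreachable.
    f <- (weight - min_adipose) / (sum(organs) + blood)
    if (f < 0.75)
      stop("weight target unreachable for this class: residual adipose ",
           round(v_adipose, 2), " L")
    organs <- organs * f
    blood <- blood * f
    v_adipose <- min_adipose
  }
  hct <- .HCT[[sex]]
  plasma <- blood * (1 - hct)
  volumes <- c(adipose = unname(v_adipose), organs)[MODEL_TISSUES]
  co <- 13 * weight^0.75 * co_mult
  perf <- .ADIPOSE_PERFUSION[[class]]
  q_adipose <- min(perf * v_adipose * flow_mult[["adipose"]], 0.4 * co)
  w <- .FLOW_WEIGHTS * flow_mult[names(.FLOW_WEIGHTS)]
  q_rest <- (co - q_adipose) * w / sum(w)
  flows <- c(adipose = unname(q_adipose), q_rest)
  bsa <- body_surface_area(weight, height)
  gfr <- mdrd_gfr(age, sex, scr, bsa) * gfr_mult
  structure(list(age = age, sex = sex, weight = weight, height = height,
                 bmi = weight / (height / 100)^2, gestational_age = 0,
                 population_class = class,
                 cardiac_output = co, hematocrit = hct,
                 serum_creatinine = scr, gfr = gfr,
                 tissue_volumes = volumes, tissue_flows = flows,
                 plasma_volume = plasma, blood_volume = blood),
            class = "subject_physiology")
}

#' Build a non-pregnant baseline population
#'
#' Samples demographics (age uniform in range, height normal per sex,
#' weight lognormal recentred exactly onto the target mean when one is
#' given) and derives tissue volumes, blood flows, hematocrit, creatinine
#' and MDRD GFR for each subject. Obese classes carry their excess weight
#' mostly as adipose volume (75%), with reduced per-volume adipose
#' perfusion. Deterministic under the spec's seed.
#'
#' @param spec a [population_spec()]; pregnancy is ignored here (see
#'   [apply_pregnancy()] / [build_population()]).
#' @return List of `subject_physiology` objects.
#' @export
build_baseline <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_subjects
  class <- spec$population_class
  vary <- spec$variability
  .with_seed(spec$seed, {
    n_f <- round(n * spec$proportion_female)
    sexes <- rep(c("female", "male"), c(n_f, n - n_f))
    ages <- if (vary) stats::runif(n, spec$age_range[1], spec$age_range[2])
            else rep(mean(spec$age_range), n)
    heights <- vapply(sexes, function(s) {
      if (!vary) return(.REF_HEIGHT[[s]])
      .REF_HEIGHT[[s]] + .HEIGHT_SD[[s]] * min(max(stats::rnorm(1), -3), 3)
    }, numeric(1))
    target <- spec$pre_pregnancy_weight
    if (is.null(target)) target <- spec$target_mean_weight
    weights <- vapply(seq_len(n), function(i) {
      mu <- if (!is.null(target)) target
            else .DEFAULT_WEIGHT[[class]][[sexes[i]]]
      mu * (if (vary) .ln_noise(1, 0.15) else 1)
    }, numeric(1))
    if (!is.null(target) && vary)
      weights <- weights * target / mean(weights)   # recentre onto target
    scrs <- vapply(sexes, function(s)
      .SCR_MEDIAN[[s]] * .ln_noise(1, if (vary) 0.15 else 0), numeric(1))
    lapply(seq_len(n), function(i) {
      co_mult <- if (vary) .ln_noise(1, 0.15) else 1
      gfr_mult <- if (vary) .ln_noise(1, 0.18) else 1
      organ_mult <- stats::setNames(.ln_noise(length(.REF_ORGANS_F),
                                              if (vary) 0.10 else 0),
                                    names(.REF_ORGANS_F))
      flow_mult <- stats::setNames(.ln_noise(length(.FLOW_WEIGHTS) + 1,
                                             if (vary) 0.20 else 0),
                                   c("adipose", names(.FLOW_WEIGHTS)))
      .assemble_subject(class, sexes[i], ages[i], weights[i], heights[i],
                        scrs[i], co_mult, gfr_mult, organ_mult, flow_mult)
    })
  })
}

#' Apply gestational scaling to a non-pregnant baseline subject
#'
#' Adds the gestational weight gain (class-specific adipose gain plus the
#' common feto-placental and maternal soft-tissue components), expands
#' plasma volume with physiologic hemodilution, scales cardiac output and
#' GFR by their gestational folds, grows adipose volume and flow, and
#' lowers serum creatinine. At `ga = 0` the subject is returned unchanged.
#' Feto-placental mass contributes to body weight but not to any
#' drug-distributing volume (no feto-placental compartments are modelled).
#'
#' @param base a non-pregnant female `subject_physiology`.
#' @param ga gestational age, weeks.
#' @return A `subject_physiology` with gestational physiology applied.
#' @export
apply_pregnancy <- function(base, ga) {
  stopifnot(inherits(base, "subject_physiology"))
  if (ga < 0) stop("gestational age must be >= 0")
  if (base$sex != "female") stop("pregnancy requires a female subject")
  if (ga == 0) return(base)
  s <- .gain_shape(ga)
  folds <- pregnancy_folds(ga)
  class <- base$population_class
  gain_adipose <- (.GAIN_TOTAL[[class]] - .GAIN_NONADIPOSE) * s
  subj <- base
  subj$gestational_age <- ga
  subj$weight <- base$weight + .GAIN_TOTAL[[class]] * s
  subj$bmi <- subj$weight / (subj$height / 100)^2
  plasma_new <- base$plasma_volume * folds$plasma_volume
  subj$plasma_volume <- plasma_new
  subj$blood_volume <- base$blood_volume +
    (plasma_new - base$plasma_volume)
  subj$hematocrit <- base$hematocrit * base$blood_volume / subj$blood_volume
  subj$tissue_volumes[["adipose"]] <-
    base$tissue_volumes[["adipose"]] + gain_adipose
  subj$tissue_volumes[["rest"]] <-
    base$tissue_volumes[["rest"]] + .GAIN_MATERNAL_SOFT * s
  subj$cardiac_output <- base$cardiac_output * folds$cardiac_output
  v_ratio <- subj$tissue_volumes[["adipose"]] /
    base$tissue_volumes[["adipose"]]
  q_adipose <- base$tissue_flows[["adipose"]] * v_ratio
  others <- setdiff(names(base$tissue_flows), "adipose")
  scale <- (subj$cardiac_output - q_adipose) /
    sum(base$tissue_flows[others])
  subj$tissue_flows[["adipose"]] <- q_adipose
  subj$tissue_flows[others] <- base$tissue_flows[others] * scale
  subj$gfr <- base$gfr * folds$gfr
  subj$serum_creatinine <- base$serum_creatinine * 0.8
  subj
}

#' Build a population, applying pregnancy when specified
#'
#' Convenience wrapper over [build_baseline()] + [apply_pregnancy()]. For a
#' pregnant spec with `target_mean_weight` (weight at GA), the baseline is
#' sampled around `target - gestational gain` so the pregnant mean lands on
#' the target.
#'
#' @param spec a [population_spec()].
#' @return List of `subject_physiology` objects.
#' @export
build_population <- function(spec) {
  if (!spec$pregnant) return(build_baseline(spec))
  ga <- spec$gestational_age
  base_spec <- spec
  if (is.null(spec$pre_pregnancy_weight) &&
      !is.null(spec$target_mean_weight)) {
    gain <- .GAIN_TOTAL[[spec$population_class]] * .gain_shape(ga)
    base_spec$pre_pregnancy_weight <- spec$target_mean_weight - gain
  }
  lapply(build_baseline(base_spec), apply_pregnancy, ga = ga)
}
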