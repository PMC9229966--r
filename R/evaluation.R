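# Model acceptance: predicted/observed ratios under the two-fold criterion
# and study-by-study report tables against the packaged clinical values.

#' Load a packaged observed clinical comparison table
#'
#' The packaged CSVs carry the printed observed statistics (AUC, serum
#' concentration at the reported time point, clearance, adipose tissue
#' concentration), the printed simulated values with 5th/95th percentiles,
#' the printed predicted/observed ratio, and a `known_failure` flag for the
#' documented out-of-two-fold adipose rows.
#'
#' @param drug `"cefazolin"` or `"cefuroxime"`.
#' @return data.frame of class `observed_dataset`.
#' @export
load_observed <- function(drug) {
  drug <- match.arg(drug, c("cefazolin", "cefuroxime"))
  path <- system.file("extdata", paste0("observed_", drug, ".csv"),
                      package = "cephpbpk")
  obs <- utils::read.csv(path, comment.char = "#",
                         colClasses = c(study_code = "character"))
  bad <- which(!is.na(obs$time_min) & obs$time_min < 0)
  if (length(bad))
    stop("observed dataset has negative sampling time in row(s) ",
         paste(bad, collapse = ", "))
  class(obs) <- c("observed_dataset", class(obs))
  obs
}

#' Two-fold acceptance ratio
#'
#' `ratio = predicted / observed`; the prediction is accepted when the
#' ratio lies within `[0.5, 2]`.
#'
#' @param predicted,observed positive values on the same scale.
#' @return List with `ratio` and logical `pass`.
#' @export
twofold_ratio <- function(predicted, observed) {
  if (!is.finite(observed) || observed <= 0)
    stop("observed value must be > 0")
  ratio <- predicted / observed
  list(ratio = ratio, pass = ratio >= 0.5 && ratio <= 2.0)
}

#' Recompute every printed predicted/observed ratio
#'
#' Arithmetic sweep over a packaged comparison table: for every row with a
#' printed observed value, printed predicted value and printed ratio, the
#' ratio is recomputed with [twofold_ratio()] and rounded to 2 decimals.
#'
#' @param drug `"cefazolin"` or `"cefuroxime"`.
#' @return data.frame with recomputed ratio, printed ratio, and agreement.
#' @export
check_printed_ratios <- function(drug) {
  obs <- load_observed(drug)
  rows <- obs[!is.na(obs$observed) & !is.na(obs$predicted) &
                !is.na(obs$printed_ratio), ]
  rows$recomputed <- vapply(seq_len(nrow(rows)), function(i)
    round(twofold_ratio(rows$predicted[i], rows$observed[i])$ratio, 2),
    numeric(1))
  rows$matches <- abs(rows$recomputed - rows$printed_ratio) < 1e-9
  rows[, c("study_code", "drug", "quantity", "matrix", "time_min",
           "observed", "predicted", "printed_ratio", "recomputed",
           "matches", "known_failure")]
}

# Mean summary series interpolated at a time point, or its maximum. Cmax
# (time_min = NA) is read from infusion end + 5 min onward: clinical peak
# samples are drawn after circulatory mixing, so the central venous
# transient during a short infusion is not an observable quantity.
.summary_value <- function(trial, output, time_min, statistic = "mean") {
  if (!output %in% names(trial$summary))
    stop("output '", output, "' was not simulated")
  series <- trial$summary[[output]][[statistic]]
  if (is.na(time_min)) {
    floor_h <- (trial$regimen$infusion_min + 5) / 60
    return(max(series[trial$time >= floor_h]))
  }
  stats::approx(trial$time, series, xout = time_min / 60)$y
}

#' Evaluate a simulated study against its observed rows
#'
#' Emits one ratio row per observed quantity: AUC (simulated mean AUC to
#' infinity), clearance (simulated mean dose/AUC), and plasma or adipose
#' concentration at each observed time (the simulated mean series linearly
#' interpolated to that time; `time_min = NA` compares against the
#' simulated maximum). Rows without an observed value are skipped; nothing
#' with an observed value is silently dropped.
#'
#' @param trial a [run_trials()] result simulated with the study's design.
#' @param obs observed rows for one study (subset of [load_observed()]).
#' @return data.frame: study_code, quantity, matrix, time_min, predicted,
#'   observed, ratio, pass, known_failure.
#' @export
evaluate_study <- function(trial, obs) {
  obs <- obs[!is.na(obs$observed), , drop = FALSE]
  if (!nrow(obs)) return(NULL)
  do.call(rbind, lapply(seq_len(nrow(obs)), function(i) {
    row <- obs[i, ]
    predicted <- switch(row$quantity,
      auc = mean(trial$endpoints$auc_inf),
      cl = mean(trial$endpoints$cl),
      conc = .summary_value(trial, row$matrix, row$time_min),
      adipose_conc = .summary_value(trial, row$matrix, row$time_min),
      stop("unknown quantity '", row$quantity, "'"))
    tf <- twofold_ratio(predicted, row$observed)
    data.frame(study_code = row$study_code, quantity = row$quantity,
               matrix = row$matrix, time_min = row$time_min,
               predicted = predicted, observed = row$observed,
               ratio = round(tf$ratio, 2), pass = tf$pass,
               known_failure = row$known_failure)
  }))
}
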