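# Reference clinical risk scores (CHA2DS2-VASc, HAS-BLED, an STS-style
# logistic surrogate) and the twin-derived POAF probability that the
# evaluation module compares against them. The STS surrogate is exactly
# that -- a configurable logistic stand-in, not the proprietary calculator.

#' CHA2DS2-VASc score
#'
#' Congestive heart failure +1, hypertension +1, age >= 75 +2, diabetes +1,
#' prior stroke/TIA +2, vascular disease +1, age 65-74 +1, female sex +1.
#'
#' @param record one or more patient records.
#' @return Integer vector, 0-9.
#' @export
cha2ds2_vasc <- function(record) {
  as.integer(
    record$chf + record$hypertension +
      2L * (record$age >= 75) + (record$age >= 65 & record$age < 75) +
      record$diabetes + 2L * record$prior_stroke_tia +
      record$vascular_disease + (record$sex == "female")
  )
}

#' HAS-BLED score
#'
#' One point each for hypertension, renal disease, liver disease, prior
#' stroke, bleeding history, labile INR, age > 65, antiplatelet/NSAID use,
#' alcohol use.
#'
#' @param record one or more patient records.
#' @return Integer vector, 0-9.
#' @export
has_bled <- function(record) {
  as.integer(
    record$hypertension + record$renal_disease + record$liver_disease +
      record$prior_stroke_tia + record$bleeding_history + record$labile_inr +
      (record$age > 65) + record$antiplatelet_use + record$alcohol_use
  )
}

#' Default coefficients of the STS-style surrogate
#' @return Named list of logistic coefficients.
#' @export
sts_surrogate_coefficients <- function() {
  list(intercept = -2.2, age_per_decade = 0.35, surgery_valve = 0.30,
       surgery_combined = 0.60, surgery_aortic = 0.50, renal_disease = 0.50,
       chf = 0.45)
}

#' STS-style logistic risk surrogate
#'
#' A configurable logistic-linear stand-in for an operative risk calculator:
#' logit(p) = intercept + age effect (per decade over 66) + surgery-type
#' effects (CABG reference) + renal disease + CHF. Not the published STS
#' model; its coefficients are proprietary and intentionally not mimicked.
#'
#' @param record one or more patient records.
#' @param coefficients named list as in
#'   \code{\link{sts_surrogate_coefficients}}.
#' @return Probability vector in [0, 1].
#' @export
sts_surrogate <- function(record, coefficients = sts_surrogate_coefficients()) {
  need <- names(sts_surrogate_coefficients())
  miss <- setdiff(need, names(coefficients))
  if (length(miss))
    stop("missing STS surrogate coefficient(s): ", paste(miss, collapse = ", "))
  lp <- coefficients$intercept +
    coefficients$age_per_decade * (record$age - 66) / 10 +
    coefficients$surgery_valve * (record$surgery_type == "valve") +
    coefficients$surgery_combined * (record$surgery_type == "combined") +
    coefficients$surgery_aortic * (record$surgery_type == "aortic") +
    coefficients$renal_disease * record$renal_disease +
    coefficients$chf * record$chf
  stats::plogis(lp)
}

#' Default coefficients of the twin POAF probability
#' @return Named list of logistic coefficients.
#' @export
twin_risk_coefficients <- function() {
  list(intercept = -1.3, vulnerability = 1.0, age_per_decade = 0.25)
}

#' Twin-derived POAF probability
#'
#' The digital-twin risk score evaluated downstream: logistic in the logit
#' of the twin's vulnerability index (so the index enters on the same scale
#' it was built on; the reference index 0.5 contributes 0) plus age.
#'
#' @param twin a \code{twin_model} or a twin table row with a
#'   \code{vulnerability} column (as from \code{\link{calibrate_cohort}});
#'   vectorized over rows.
#' @param record the matching patient record(s).
#' @param coefficients named list as in \code{\link{twin_risk_coefficients}}.
#' @return Probability vector in [0, 1].
#' @export
twin_risk_probability <- function(twin, record,
                                  coefficients = twin_risk_coefficients()) {
  vuln <- if (inherits(twin, "twin_model")) {
    if (!isTRUE(twin$converged))
      warning("twin ", twin$patient_id,
              " is non-converged; probability uses best-so-far calibration")
    vulnerability_index(twin, record)
  } else twin$vulnerability
  lp <- coefficients$intercept +
    coefficients$vulnerability * stats::qlogis(vuln) +
    coefficients$age_per_decade * (record$age - 66) / 10
  stats::plogis(lp)
}

#' Score panel for a cohort
#'
#' @param cohort patient records.
#' @param twins twin table aligned with \code{cohort} (rows match).
#' @return data.frame keyed by \code{patient_id} with \code{chads_vasc},
#'   \code{has_bled}, \code{sts_surrogate}, \code{twin_prob}.
#' @export
score_panel <- function(cohort, twins) {
  stopifnot(nrow(cohort) == nrow(twins),
            all(cohort$id == twins$patient_id))
  data.frame(patient_id = cohort$id,
             chads_vasc = cha2ds2_vasc(cohort),
             has_bled = has_bled(cohort),
             sts_surrogate = sts_surrogate(cohort),
             twin_prob = twin_risk_probability(twins, cohort),
             stringsAsFactors = FALSE)
}
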