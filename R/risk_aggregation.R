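#' Redistribute aggregation weights over absent findings
#'
#' Base weights are assigned to the three Symbolic Risks (equal thirds
#' by default, overridable by the medical team). When a finding group is
#' absent, its risk is null and its base weight is redistributed
#' equitably among the remaining risks, so the weights always sum to 1
#' and null risks carry weight 0.
#'
#' @param base Numeric base weights `c(w1, w2, w3)`, nonnegative,
#'   summing to 1 (within 1e-9).
#' @param null_flags Logical vector of length 3: is each risk null?
#' @return Redistributed weights summing to 1.
#' @export
#' @examples
#' redistribute_weights(null_flags = c(FALSE, FALSE, TRUE))  # 0.5, 0.5, 0
redistribute_weights <- function(base = rep(1, 3) / 3, null_flags) {
  stopifnot(length(base) == 3, length(null_flags) == 3, is.logical(null_flags))
  if (any(base < 0) || abs(sum(base) - 1) > 1e-9) {
    stop("base weights must be nonnegative and sum to 1", call. = FALSE)
  }
  if (all(null_flags)) {
    stop("no findings to aggregate: all three risks are null", call. = FALSE)
  }
  w <- base
  spare <- sum(w[null_flags])
  w[null_flags] <- 0
  w[!null_flags] <- w[!null_flags] + spare / sum(!null_flags)
  w
}

#' Global Risk aggregation
#'
#' The Global Risk is the weighted sum of the Symbolic Risks multiplied
#' by the decimal logarithm of the Statistical Risk,
#' \deqn{R_G = (\omega_1 R_1 + \omega_2 R_2 + \omega_3 R_3)\cdot
#'       \log_{10} R_s,}
#' clamped to \[0, 100\]: the multiplicative statistical term can push
#' the raw product past the scale, in which case the Global Risk takes
#' its maximum value of one hundred. Null risks contribute zero, and
#' `Rs` is floored at 1 so the log term is never negative (the
#' statistical term is risk-increasing by design).
#'
#' @param risks A `symbolic_risk_set` (or plain list `R1`/`R2`/`R3`,
#'   `NULL` for absent groups).
#' @param weights Redistributed weights from [redistribute_weights()].
#' @param Rs Statistical Risk in \[0, 100\].
#' @return Global Risk in \[0, 100\].
#' @export
global_risk <- function(risks, weights, Rs) {
  stopifnot(length(weights) == 3, Rs >= 0, Rs <= 100)
  r <- vapply(risks[c("R1", "R2", "R3")],
              function(v) if (is.null(v)) 0 else as.numeric(v), numeric(1))
  if (any(r < 0 | r > 100)) stop("Symbolic Risks must lie in [0, 100]", call. = FALSE)
  raw <- sum(weights * r) * log10(max(Rs, 1))
  min(max(raw, 0), 100)
}

#' Correction parameters for the BI-RADS-ordered weighting factor
#'
#' Maps each BI-RADS category to a numeric level and a correction
#' branch: categories 1-2 attenuate the Global Risk, 3-4C amplify it
#' (capped so the corrected risk cannot exceed 100), and 5-6 saturate it
#' to the maximum. Sub-categories 4A/4B/4C take their ordinal positions
#' (4, 5, 6) as numeric levels; both maps are configurable.
#'
#' @param levels Named numeric vector BI-RADS category -> numeric level.
#' @return A `correction_params` object.
#' @export
correction_params <- function(levels = c("1" = 1, "2" = 2, "3" = 3,
                                         "4A" = 4, "4B" = 5, "4C" = 6,
                                         "5" = 7, "6" = 8)) {
  branch <- c("1" = "attenuate", "2" = "attenuate",
              "3" = "amplify", "4A" = "amplify", "4B" = "amplify",
              "4C" = "amplify", "5" = "saturate", "6" = "saturate")
  structure(list(levels = levels, branch = branch), class = "correction_params")
}

#' BI-RADS weighting factor Fp for the Global Risk correction
#'
#' With `f(RG) = 10 / (RG + 10)`:
#' * attenuate (BI-RADS 1-2): `Fp = 1 / (k + f(RG))`, `k = -level + 3.5`;
#' * amplify (BI-RADS 3-4C): `Fp = t + f(RG)`, `t = level - 1.5`, capped
#'   at `Fc = 100 / RG` whenever `Fc <= Fp` so the corrected risk cannot
#'   exceed one hundred;
#' * saturate (BI-RADS 5-6): `Fp = 100 / RG`.
#'
#' @param birads BI-RADS category (`"1"` ... `"6"`, incl. `"4A"/"4B"/"4C"`).
#'   Category 0 denotes an incomplete study and has no defined correction.
#' @param RG Global Risk in \[0, 100\].
#' @param params A [correction_params()] object.
#' @return Positive weighting factor Fp.
#' @export
correction_factor <- function(birads, RG, params = correction_params()) {
  birads <- .canon_category("birads", birads)
  if (is.null(birads)) stop("invalid BI-RADS category", call. = FALSE)
  if (birads == "0") {
    stop("BI-RADS 0 marks an incomplete study: no correction is defined; ",
         "complete the imaging work-up first", call. = FALSE)
  }
  if (RG < 0 || RG > 100) stop("RG must lie in [0, 100]", call. = FALSE)
  if (RG == 0) {
    warning("Global Risk is 0; correction skipped (Fp = 1)", call. = FALSE)
    return(1)
  }
  level <- params$levels[[birads]]
  f_rg <- 10 / (RG + 10)
  switch(params$branch[[birads]],
    attenuate = 1 / ((-level + 3.5) + f_rg),
    amplify = {
      fp <- (level - 1.5) + f_rg
      fc <- 100 / RG
      if (fc <= fp) fc else fp
    },
    saturate = 100 / RG)
}

#' Corrected Global Risk
#'
#' `RG' = RG * Fp`, with an absolute maximum of one hundred.
#'
#' @param RG Global Risk in \[0, 100\].
#' @param Fp Weighting factor from [correction_factor()] (positive).
#' @return Corrected Global Risk in \[0, 100\].
#' @export
corrected_global_risk <- function(RG, Fp) {
  stopifnot(Fp > 0, RG >= 0, RG <= 100)
  min(RG * Fp, 100)
}

#' Warning state from the Corrected Global Risk
#'
#' Half-open thresholds: healthy below 40, dubious in \[40, 60), and a
#' potential breast-cancer case at 60 or above (maximum alert at 100).
#'
#' @param RG_corrected Corrected Global Risk in \[0, 100\].
#' @param thresholds Numeric `c(dubious = 40, potential = 60)`.
#' @return One of `"healthy"`, `"dubious"`, `"potential"`.
#' @export
classify_state <- function(RG_corrected, thresholds = c(dubious = 40, potential = 60)) {
  stopifnot(RG_corrected >= 0, RG_corrected <= 100,
            thresholds[["dubious"]] < thresholds[["potential"]])
  if (RG_corrected < thresholds[["dubious"]]) "healthy"
  else if (RG_corrected < thresholds[["potential"]]) "dubious"
  else "potential"
}

#' Clinical recommendation for a warning state
#'
#' @param state A state from [classify_state()].
#' @return Recommendation string.
#' @export
state_recommendation <- function(state) {
  switch(match.arg(state, c("healthy", "dubious", "potential")),
    healthy = "Refer the patient for routine review.",
    dubious = paste("Reconsider the patient's case; consider performing other",
                    "tests and summoning the patient for a new visit."),
    potential = "Perform confirmatory tests.")
}

#' Full per-patient risk profile (Stages 2-4)
#'
#' Runs the complete pipeline for one patient: the three Symbolic Risks,
#' the Statistical Risk, weight redistribution over absent findings,
#' Global Risk aggregation, BI-RADS correction and state classification.
#' All intermediate quantities are kept in the profile so clinicians can
#' inspect the uncorrected prediction alongside the BI-RADS-weighted one.
#'
#' A findings-free mammogram (all three groups absent) never reaches the
#' aggregation formula: its Global Risk is reported as 0 with state
#' `"healthy"` and an explicit `"no findings"` annotation.
#'
#' @param record A validated `patient_record`.
#' @param model A trained `risk_classifier` (may be `NULL` when `Rs` is
#'   supplied directly).
#' @param specs The three expert systems ([default_expert_systems()]).
#' @param base_weights Base aggregation weights (default equal thirds).
#' @param correction A [correction_params()] object.
#' @param thresholds State thresholds for [classify_state()].
#' @param override Optional list with any of `R1`, `R2`, `R3`, `Rs` to
#'   replace computed risks (e.g. to reproduce a published worked
#'   example with an externally fixed rule base).
#' @return A `risk_profile` list: `risks`, `weights`, `Rs`, `RG`, `Fp`,
#'   `RG_corrected`, `state`, `recommendation`, `annotation`.
#' @export
risk_profile <- function(record, model = NULL,
                         specs = default_expert_systems(),
                         base_weights = rep(1, 3) / 3,
                         correction = correction_params(),
                         thresholds = c(dubious = 40, potential = 60),
                         override = list()) {
  risks <- assess_all(record, specs)
  for (k in c("R1", "R2", "R3")) {
    if (k %in% names(override)) risks[[k]] <- override[[k]]
  }
  Rs <- if (!is.null(override$Rs)) override$Rs
        else if (!is.null(model)) predict_statistical_risk(model, record)
        else stop("either a trained model or an Rs override is required",
                  call. = FALSE)

  nulls <- vapply(risks[c("R1", "R2", "R3")], is.null, logical(1))
  annotation <- NULL
  if (all(nulls)) {
    w <- c(0, 0, 0)
    RG <- 0
    Fp <- NA_real_
    RGc <- 0
    annotation <- "no findings: mammogram shows no mass, calcification, asymmetry or distortion"
  } else {
    w <- redistribute_weights(base_weights, nulls)
    RG <- global_risk(risks, w, Rs)
    Fp <- if (RG == 0) suppressWarnings(correction_factor(record$birads, RG, correction))
          else correction_factor(record$birads, RG, correction)
    RGc <- corrected_global_risk(RG, Fp)
  }
  state <- classify_state(RGc, thresholds)
  structure(list(
    patient_id = record$patient_id, birads = record$birads,
    risks = risks, weights = w, Rs = Rs, RG = RG, Fp = Fp,
    RG_corrected = RGc, state = state,
    recommendation = state_recommendation(state),
    annotation = annotation),
    class = "risk_profile")
}

#' @export
print.risk_profile <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "null" else sprintf("%.2f", v)
  cat("<risk_profile>", x$patient_id, "(BI-RADS", paste0(x$birads, ")"), "\n")
  cat(sprintf("  Symbolic Risks: R1 = %s, R2 = %s, R3 = %s\n",
              fmt(x$risks$R1), fmt(x$risks$R2), fmt(x$risks$R3)))
  cat(sprintf("  weights: (%.3f, %.3f, %.3f)   Statistical Risk Rs = %.2f\n",
              x$weights[1], x$weights[2], x$weights[3], x$Rs))
  cat(sprintf("  Global Risk = %.2f   Fp = %s   Corrected Global Risk = %.2f\n",
              x$RG, ifelse(is.na(x$Fp), "-", sprintf("%.4f", x$Fp)),
              x$RG_corrected))
  cat(sprintf("  state: %s -- %s\n", x$state, x$recommendation))
  if (!is.null(x$annotation)) cat(" ", x$annotation, "\n")
  invisible(x)
}
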