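#' Symbolic Risks from the three concurrent expert systems
#'
#' Each finding group of a mammogram report (masses; calcifications;
#' asymmetries and architectural distortion) is scored by its own
#' Mamdani expert system into a Symbolic Risk in \[0, 100\]. A risk is
#' `NULL` precisely when the finding group is absent -- absence is
#' decided by the report's present/absent flags, never by a computed
#' zero, since a present but benign-looking finding can legitimately
#' score small-but-nonzero. For the third system, the risk is `NULL`
#' only when both asymmetry and distortion are absent.
#'
#' @name symbolic_risk
NULL

.infer_or_config_error <- function(spec, inputs) {
  tryCatch(infer(spec, inputs), error = function(e) {
    if (grepl("no rule fired", conditionMessage(e))) {
      stop(sprintf("rule base '%s' does not cover input combination (%s)",
                   spec$name,
                   paste(names(inputs), inputs, sep = "=", collapse = ", ")),
           call. = FALSE)
    }
    stop(e)
  })
}

#' Symbolic Risk R1 for masses
#'
#' @param record A validated `patient_record`.
#' @param spec Expert system with input variables `shape`, `margins`,
#'   `density`; defaults to the bundled masses rule base.
#' @return Risk in \[0, 100\], or `NULL` when no mass is present.
#' @export
assess_masses <- function(record, spec = NULL) {
  if (!isTRUE(record$mass_present)) return(NULL)
  if (is.null(spec)) spec <- default_expert_systems()$masses
  .infer_or_config_error(spec, c(shape = record$mass_shape,
                                 margins = record$mass_margins,
                                 density = record$mass_density))
}

#' Symbolic Risk R2 for calcifications
#'
#' @param record A validated `patient_record`.
#' @param spec Expert system with input variables `type`, `shape`,
#'   `distribution`; defaults to the bundled calcifications rule base.
#' @return Risk in \[0, 100\], or `NULL` when no calcifications are present.
#' @export
assess_calcifications <- function(record, spec = NULL) {
  if (!isTRUE(record$calc_present)) return(NULL)
  if (is.null(spec)) spec <- default_expert_systems()$calcifications
  .infer_or_config_error(spec, c(type = record$calc_type,
                                 shape = record$calc_shape,
                                 distribution = record$calc_distribution))
}

#' Symbolic Risk R3 for asymmetries and architectural distortion
#'
#' The four antecedents are the two present/absent flags and the two
#' type descriptors; an absent sub-group's type is passed as `"none"`.
#'
#' @param record A validated `patient_record`.
#' @param spec Expert system over `asymmetry`, `asymmetry_type`,
#'   `distortion`, `distortion_type`; defaults to the bundled rule base.
#' @return Risk in \[0, 100\], or `NULL` when both asymmetry and
#'   distortion are absent.
#' @export
assess_asymmetry_distortion <- function(record, spec = NULL) {
  if (!isTRUE(record$asymmetry_present) && !isTRUE(record$distortion_present)) {
    return(NULL)
  }
  if (is.null(spec)) spec <- default_expert_systems()$asymmetry_distortion
  .infer_or_config_error(spec, c(
    asymmetry = if (record$asymmetry_present) "present" else "absent",
    asymmetry_type = record$asymmetry_type,
    distortion = if (record$distortion_present) "present" else "absent",
    distortion_type = record$distortion_type))
}

#' All three Symbolic Risks for one patient
#'
#' The three expert systems run independently (concurrently in the
#' conceptual pipeline); evaluation order does not matter.
#'
#' @param record A validated `patient_record`.
#' @param specs Named list of the three expert systems, as returned by
#'   [default_expert_systems()].
#' @return A `symbolic_risk_set`: `list(R1 = , R2 = , R3 = )` where each
#'   element is a risk in \[0, 100\] or `NULL` for an absent group.
#' @export
assess_all <- function(record, specs = default_expert_systems()) {
  structure(list(
    R1 = assess_masses(record, specs$masses),
    R2 = assess_calcifications(record, specs$calcifications),
    R3 = assess_asymmetry_distortion(record, specs$asymmetry_distortion)),
    class = "symbolic_risk_set")
}

#' @export
print.symbolic_risk_set <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "null (finding absent)" else sprintf("%.2f", v)
  cat("<symbolic_risk_set>\n")
  cat("  R1 (masses):                 ", fmt(x$R1), "\n")
  cat("  R2 (calcifications):         ", fmt(x$R2), "\n")
  cat("  R3 (asymmetry/distortion):   ", fmt(x$R3), "\n")
  invisible(x)
}
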