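#' Validate and canonicalize a raw patient record
#'
#' Takes a named list (or one-row data frame) of raw field values and
#' returns a canonical `patient_record`. Categorical values are matched
#' case-insensitively against the BI-RADS lexicon vocabularies (see
#' [record_vocabulary()]), aliases are resolved, present/absent flags are
#' parsed from common spellings, and the absent-group consistency rules
#' are enforced: when a finding group is absent its sub-descriptors must
#' be (or are filled in as) `"none"`; any other explicit value is an
#' error, since it signals a contradictory report.
#'
#' @param raw Named list or one-row data frame supplying all mandatory
#'   fields (`label` is the only optional field).
#' @return A `patient_record`: a named list with canonical values,
#'   logical flags and numeric age. Validation is idempotent.
#' @export
#' @examples
#' rec <- validate_record(list(
#'   patient_id = "p1", age = 65, personal_history = "no",
#'   family_history = "none", mass_present = "present",
#'   mass_shape = "Irregular", mass_margins = "spiculated",
#'   mass_density = "Homogeneous", calc_present = "absent",
#'   asymmetry_present = "absent", distortion_present = "absent",
#'   breast_density = "heterogeneously dense", birads = "4B"))
#' rec$mass_density  # "equal density" (canonical alias)
validate_record <- function(raw) {
  if (is.data.frame(raw)) {
    stopifnot(nrow(raw) == 1)
    raw <- as.list(raw)
  }
  if (!is.list(raw) || is.null(names(raw))) {
    stop("raw record must be a named list or one-row data frame", call. = FALSE)
  }
  voc <- record_vocabulary()
  get <- function(f) if (f %in% names(raw)) raw[[f]] else NULL

  rec <- list()

  id <- get("patient_id")
  if (is.null(id) || is.na(id) || !nzchar(trimws(as.character(id)))) {
    stop("missing mandatory field 'patient_id'", call. = FALSE)
  }
  rec$patient_id <- trimws(as.character(id))

  age <- suppressWarnings(as.numeric(get("age")))
  if (length(age) != 1 || is.na(age)) {
    stop("missing or non-numeric mandatory field 'age'", call. = FALSE)
  }
  if (age <= 0 || age >= 130) {
    stop(sprintf("invalid value for field 'age': %s (must be in (0, 130))", age),
         call. = FALSE)
  }
  rec$age <- age

  # present/absent flags first: they gate their sub-fields
  flags <- list()
  for (f in .flag_fields) {
    v <- get(f)
    if (is.null(v) || (length(v) == 1 && is.na(v))) {
      stop(sprintf("missing mandatory field '%s'", f), call. = FALSE)
    }
    parsed <- .parse_flag(v)
    if (is.null(parsed)) {
      stop(sprintf("invalid value for field '%s': \"%s\"", f, v), call. = FALSE)
    }
    flags[[f]] <- parsed
  }

  canon_one <- function(field, mandatory = TRUE) {
    v <- get(field)
    if (is.null(v) || (length(v) == 1 && (is.na(v) || !nzchar(trimws(as.character(v)))))) {
      if (mandatory) stop(sprintf("missing mandatory field '%s'", field), call. = FALSE)
      return(NA_character_)
    }
    cv <- .canon_category(field, v)
    if (is.null(cv)) {
      stop(sprintf("invalid value for field '%s': \"%s\" (allowed: %s)",
                   field, v, paste(voc[[field]], collapse = ", ")),
           call. = FALSE)
    }
    cv
  }

  rec$personal_history <- canon_one("personal_history")
  rec$family_history <- canon_one("family_history")

  for (flag in .flag_fields) {
    rec[[flag]] <- flags[[flag]]
    for (sub in .finding_groups[[flag]]) {
      v <- get(sub)
      empty <- is.null(v) ||
        (length(v) == 1 && (is.na(v) || tolower(trimws(as.character(v))) %in% c("", "-", "none")))
      if (!flags[[flag]]) {
        if (!empty) {
          stop(sprintf(
            "inconsistent record: '%s' is absent but '%s' = \"%s\" (expected \"none\")",
            flag, sub, v), call. = FALSE)
        }
        rec[[sub]] <- "none"
      } else {
        rec[[sub]] <- canon_one(sub)
      }
    }
  }

  rec$breast_density <- canon_one("breast_density")
  rec$birads <- canon_one("birads")
  rec$label <- canon_one("label", mandatory = FALSE)

  structure(rec[.record_fields], class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record>", x$patient_id, "\n")
  cat("  age:", x$age, " BI-RADS:", x$birads,
      if (!is.na(x$label)) paste(" label:", x$label) else "", "\n")
  for (flag in .flag_fields) {
    subs <- .finding_groups[[flag]]
    cat(sprintf("  %s: %s", sub("_present$", "", flag),
                if (x[[flag]]) paste(unlist(x[subs]), collapse = " / ") else "absent"),
        "\n")
  }
  invisible(x)
}

#' Construct a cohort of validated patient records
#'
#' @param records Data frame of canonical records (one row per patient,
#'   columns as in [record_vocabulary()] plus `patient_id`, `age`, flags)
#'   or a list of `patient_record` objects.
#' @param provenance Free-text note recording where the cohort came from
#'   (source file, or generator parameters).
#' @return A `cohort` object.
#' @export
new_cohort <- function(records, provenance = "") {
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, lapply(records, function(r) {
      as.data.frame(unclass(r), stringsAsFactors = FALSE)
    }))
  }
  if (is.null(records) || nrow(records) == 0) {
    records <- as.data.frame(
      stats::setNames(rep(list(character(0)), length(.record_fields)), .record_fields),
      stringsAsFactors = FALSE)
    records$age <- numeric(0)
    for (f in .flag_fields) records[[f]] <- logical(0)
  }
  stopifnot(identical(names(records), .record_fields))
  if (anyDuplicated(records$patient_id)) {
    dup <- unique(records$patient_id[duplicated(records$patient_id)])
    stop("duplicate patient_id values in cohort: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  rownames(records) <- NULL
  structure(list(records = records, provenance = provenance), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n <- nrow(x$records)
  labs <- x$records$label
  cat(sprintf("<cohort> %d records (%d cancer / %d non-cancer / %d unlabeled)\n",
              n, sum(labs == "cancer", na.rm = TRUE),
              sum(labs == "non-cancer", na.rm = TRUE), sum(is.na(labs))))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
as.data.frame.cohort <- function(x, ...) x$records

#' Number of records in a cohort
#' @param cohort A `cohort`.
#' @return Integer count.
#' @export
cohort_size <- function(cohort) nrow(cohort$records)

#' Extract one record from a cohort
#' @param cohort A `cohort`.
#' @param i Row index.
#' @return A `patient_record`.
#' @export
cohort_record <- function(cohort, i) {
  row <- as.list(cohort$records[i, , drop = FALSE])
  row$label <- if (is.na(row$label)) NA_character_ else row$label
  structure(row, class = "patient_record")
}

#' Read a patient cohort from CSV or JSON
#'
#' CSV files are comma-separated UTF-8 with a mandatory header using the
#' canonical field names; the literal string `"NA"` is a category of the
#' history fields, not a missing value (an empty cell marks a missing
#' label). JSON files may hold a single patient object, an array of
#' patients, or an object `{"provenance": ..., "records": [...]}`.
#' Every row passes through [validate_record()]; failures are collected
#' and reported together with their row numbers.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; guessed from the extension when missing.
#' @return A [new_cohort()] object.
#' @export
read_cohort <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  prov <- ""
  if (format == "csv") {
    df <- tryCatch(
      utils::read.csv(path, colClasses = "character", na.strings = "",
                      check.names = FALSE, fileEncoding = "UTF-8"),
      error = function(e) stop("malformed CSV file: ", conditionMessage(e), call. = FALSE))
    missing_cols <- setdiff(setdiff(.record_fields, "label"), names(df))
    if (length(missing_cols) > 0) {
      stop("CSV is missing required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    if (!"label" %in% names(df)) df$label <- NA_character_
    rows <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  } else {
    doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                    error = function(e) stop("malformed JSON file: ",
                                             conditionMessage(e), call. = FALSE))
    prov <- ""
    if (is.list(doc) && !is.null(doc$records)) {
      prov <- if (!is.null(doc$provenance)) as.character(doc$provenance) else ""
      rows <- doc$records
    } else if (is.list(doc) && !is.null(doc$patient_id)) {
      rows <- list(doc)  # single-patient document
    } else {
      rows <- doc
    }
  }

  recs <- vector("list", length(rows))
  errs <- character(0)
  for (i in seq_along(rows)) {
    recs[[i]] <- tryCatch(validate_record(rows[[i]]), error = function(e) {
      errs <<- c(errs, sprintf("row %d: %s", i, conditionMessage(e)))
      NULL
    })
  }
  if (length(errs) > 0) {
    stop("invalid cohort (", length(errs), " bad row(s)):\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  prov_note <- if (nzchar(prov)) prov else path
  new_cohort(recs, provenance = prov_note)
}

#' Write a cohort to CSV or JSON
#'
#' Writing then reading back reproduces the cohort field-for-field
#' (round-trip identity on canonicalized cohorts).
#'
#' @param cohort A `cohort`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; guessed from the extension when missing.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- cohort$records
  if (format == "csv") {
    out <- df
    for (f in .flag_fields) out[[f]] <- ifelse(out[[f]], "true", "false")
    ok <- tryCatch({
      utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE,
                       fileEncoding = "UTF-8")
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write file: ", path, call. = FALSE)
  } else {
    doc <- list(provenance = cohort$provenance,
                records = lapply(seq_len(nrow(df)), function(i) {
                  r <- as.list(df[i, , drop = FALSE])
                  if (is.na(r$label)) r$label <- NULL
                  r
                }))
    ok <- tryCatch({
      jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("cannot write file: ", path, call. = FALSE)
  }
  invisible(path)
}
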