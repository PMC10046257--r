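#' Controlled vocabularies for the patient record schema
#'
#' The descriptor fields of a screening record follow the BI-RADS
#' mammography lexicon: each categorical field takes a value from a fixed
#' vocabulary. Values are matched case-insensitively and a small alias
#' table maps common alternative spellings (e.g. `"popcorn"` for the
#' coarse calcification shape, `"homogeneous"` for equal mass density)
#' onto the canonical form.
#'
#' @return A named list mapping each categorical field name to its
#'   character vector of canonical values, ordered from least to most
#'   suspicious where the field has a natural ordinal reading.
#' @export
#' @examples
#' record_vocabulary()$mass_shape
record_vocabulary <- function() {
  list(
    personal_history  = c("no", "yes", "NA"),
    family_history    = c("none", "minor", "major", "NA"),
    mass_shape        = c("none", "oval", "round", "lobulated", "irregular"),
    mass_margins      = c("none", "circumscribed", "obscured",
                          "micro-lobulated", "indistinct", "spiculated"),
    mass_density      = c("none", "low density", "equal density",
                          "high density"),
    calc_type         = c("none", "primary", "associated"),
    calc_shape        = c("none", "skin", "vascular", "coarse",
                          "large rod-like", "round", "rim", "dystrophic",
                          "milk of calcium", "suture", "amorphous",
                          "coarse heterogeneous", "fine pleomorphic",
                          "fine linear", "fine linear branching"),
    calc_distribution = c("none", "diffuse", "regional", "grouped",
                          "linear", "segmental"),
    asymmetry_type    = c("none", "missing", "focal", "developing"),
    distortion_type   = c("none", "primary", "associated"),
    breast_density    = c("missing", "fatty", "scattered fibroglandular",
                          "heterogeneously dense", "extremely dense"),
    birads            = c("0", "1", "2", "3", "4A", "4B", "4C", "5", "6"),
    label             = c("cancer", "non-cancer")
  )
}

# alias -> canonical, applied after lower-casing (birads is upper-cased)
.vocab_aliases <- list(
  personal_history = c("n/a" = "NA", "na" = "NA"),
  family_history   = c("n/a" = "NA", "na" = "NA"),
  mass_density     = c("homogeneous" = "equal density"),
  calc_shape       = c(
    'coarse or "popcorn-like"'          = "coarse",
    "coarse or popcorn-like"            = "coarse",
    "popcorn"                           = "coarse",
    "popcorn-like"                      = "coarse",
    "fine linear or fine linear branching" = "fine linear branching",
    "milk-of-calcium"                   = "milk of calcium"
  ),
  breast_density   = c(
    "scattered areas of fibro glandular" = "scattered fibroglandular",
    "scattered areas of fibroglandular"  = "scattered fibroglandular",
    "scattered"                          = "scattered fibroglandular"
  ),
  birads           = c("4.A" = "4A", "4.B" = "4B", "4.C" = "4C"),
  label            = c("noncancer" = "non-cancer", "non cancer" = "non-cancer",
                       "healthy" = "non-cancer", "control" = "non-cancer")
)

# flag fields and the sub-fields they gate
.finding_groups <- list(
  mass_present       = c("mass_shape", "mass_margins", "mass_density"),
  calc_present       = c("calc_type", "calc_shape", "calc_distribution"),
  asymmetry_present  = "asymmetry_type",
  distortion_present = "distortion_type"
)

# canonical column order for records, cohort files and JSON documents
.record_fields <- c(
  "patient_id", "age", "personal_history", "family_history",
  "mass_present", "mass_shape", "mass_margins", "mass_density",
  "calc_present", "calc_type", "calc_shape", "calc_distribution",
  "asymmetry_present", "asymmetry_type",
  "distortion_present", "distortion_type",
  "breast_density", "birads", "label"
)

.flag_fields <- names(.finding_groups)

#' @keywords internal
.canon_category <- function(field, value) {
  if (is.null(value) || length(value) != 1 || is.na(value)) return(NA_character_)
  v <- trimws(as.character(value))
  v <- if (field == "birads") toupper(v) else {
    # "NA" category for histories keeps its capitalisation
    low <- tolower(v)
    if (low == "na" && field %in% c("personal_history", "family_history")) "NA" else low
  }
  al <- .vocab_aliases[[field]]
  if (!is.null(al)) {
    hit <- match(tolower(v), tolower(names(al)))
    if (!is.na(hit)) v <- unname(al[hit])
  }
  voc <- record_vocabulary()[[field]]
  hit <- match(tolower(v), tolower(voc))
  if (is.na(hit)) return(NULL)  # signals a vocabulary violation
  voc[hit]
}

#' @keywords internal
.parse_flag <- function(value) {
  if (is.logical(value) && length(value) == 1 && !is.na(value)) return(value)
  v <- tolower(trimws(as.character(value)))
  if (v %in% c("true", "t", "yes", "present", "1")) return(TRUE)
  if (v %in% c("false", "f", "no", "absent", "0")) return(FALSE)
  NULL
}
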