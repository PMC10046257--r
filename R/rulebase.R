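#' Ordinal suspicion scores behind the default rule bases
#'
#' The default rule bases are generated from documented ordinal
#' orderings of the BI-RADS lexicon: each category carries a suspicion
#' score (0 = absent/typically benign, larger = more suspicious of
#' malignancy), e.g. mass shape `none < oval = round < lobulated <
#' irregular` and margins `circumscribed < obscured < micro-lobulated <
#' indistinct < spiculated`; typically-benign calcification shapes score
#' low while amorphous/coarse-heterogeneous are intermediate and fine
#' pleomorphic / fine linear (branching) score highest. Mass density
#' acts only as a minor modifier. A rule is emitted for every point of
#' the categorical input grid (so the rule base is total), mapping the
#' normalized score sum onto the five consequent labels.
#'
#' @return Named list (one entry per expert system) of named lists
#'   mapping each antecedent variable's categories to suspicion scores.
#' @export
suspicion_ordinals <- function() {
  list(
    masses = list(
      shape   = c("none" = 0, "oval" = 1, "round" = 1, "lobulated" = 2,
                  "irregular" = 3),
      margins = c("none" = 0, "circumscribed" = 1, "obscured" = 2,
                  "micro-lobulated" = 3, "indistinct" = 4, "spiculated" = 5),
      density = c("none" = 0, "low density" = 0, "equal density" = 1,
                  "high density" = 2)
    ),
    calcifications = list(
      type         = c("none" = 0, "primary" = 1, "associated" = 1),
      shape        = c("none" = 0, "skin" = 1, "vascular" = 1, "coarse" = 1,
                       "large rod-like" = 1, "round" = 1, "rim" = 1,
                       "dystrophic" = 1, "milk of calcium" = 1, "suture" = 1,
                       "amorphous" = 3, "coarse heterogeneous" = 3,
                       "fine pleomorphic" = 4, "fine linear" = 4,
                       "fine linear branching" = 5),
      distribution = c("none" = 0, "diffuse" = 1, "regional" = 2,
                       "grouped" = 3, "linear" = 4, "segmental" = 5)
    ),
    asymmetry_distortion = list(
      asymmetry       = c("absent" = 0, "present" = 1),
      asymmetry_type  = c("none" = 0, "missing" = 1, "focal" = 2,
                          "developing" = 3),
      distortion      = c("absent" = 0, "present" = 1),
      distortion_type = c("none" = 0, "primary" = 2, "associated" = 3)
    )
  )
}

# five consequent labels, peaks 0/25/50/75/100, half-width 25,
# shoulders clipped at the universe edges
.default_consequents <- function() {
  list("very-low"  = c(0, 0, 25),
       "low"       = c(0, 25, 50),
       "medium"    = c(25, 50, 75),
       "high"      = c(50, 75, 100),
       "very-high" = c(75, 100, 100))
}

#' Build one of the bundled default rule bases
#'
#' Enumerates the full categorical grid of the system's antecedents,
#' scores each combination by its summed suspicion ordinals (see
#' [suspicion_ordinals()]), and maps the normalized score onto the five
#' ordered consequent labels by equal-width bins. The resulting rule
#' base is total (every combination fires exactly one rule) and
#' monotone: raising any single antecedent to a more suspicious
#' category never lowers the consequent label.
#'
#' @param system One of `"masses"`, `"calcifications"`,
#'   `"asymmetry_distortion"`.
#' @return An [expert_system()].
#' @export
build_default_rule_base <- function(system = c("masses", "calcifications",
                                               "asymmetry_distortion")) {
  system <- match.arg(system)
  ords <- suspicion_ordinals()[[system]]
  inputs <- lapply(ords, names)
  output_name <- switch(system, masses = "R1", calcifications = "R2",
                        asymmetry_distortion = "R3")
  labels <- names(.default_consequents())
  max_score <- sum(vapply(ords, max, numeric(1)))

  grid <- expand.grid(inputs, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  rules <- lapply(seq_len(nrow(grid)), function(i) {
    combo <- vapply(names(ords), function(v) grid[[v]][i], character(1))
    score <- sum(vapply(names(ords), function(v) ords[[v]][[combo[[v]]]],
                        numeric(1)))
    bin <- min(length(labels), floor(score / max_score * length(labels)) + 1L)
    list(when = combo, then = labels[bin])
  })
  expert_system(system, inputs, output_name, .default_consequents(), rules)
}

#' Path to a bundled rule-base file
#'
#' The three default rule bases ship as editable YAML files so a medical
#' team can adapt the rules without touching code.
#'
#' @param system Rule-base name, as in [build_default_rule_base()].
#' @return File path inside the installed package.
#' @export
default_rule_base_path <- function(system = c("masses", "calcifications",
                                              "asymmetry_distortion")) {
  system <- match.arg(system)
  path <- system.file("extdata", "rules", paste0(system, ".yaml"),
                      package = "mammorisk")
  if (!nzchar(path)) stop("bundled rule base not found: ", system, call. = FALSE)
  path
}

#' Load the three bundled expert systems
#'
#' @param paths Optional named list/vector of file paths overriding the
#'   bundled rule bases (names `masses`, `calcifications`,
#'   `asymmetry_distortion`).
#' @return Named list of three [expert_system()] objects.
#' @export
default_expert_systems <- function(paths = NULL) {
  systems <- c("masses", "calcifications", "asymmetry_distortion")
  out <- lapply(systems, function(s) {
    p <- if (!is.null(paths) && !is.null(paths[[s]])) paths[[s]]
         else default_rule_base_path(s)
    load_expert_system(p)
  })
  stats::setNames(out, systems)
}
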