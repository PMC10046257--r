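#' Mamdani fuzzy expert systems over categorical antecedents
#'
#' The inference engine follows the classic Mamdani configuration:
#' MIN implication (each rule's consequent fuzzy set is clipped at the
#' rule's firing strength), MAX aggregation (the clipped sets are
#' combined pointwise), and centroid defuzzification on a uniform
#' discretization of the output universe \[0, 100\]. Antecedents are
#' singleton membership functions over category labels -- the natural
#' choice for the BI-RADS lexicon, where a finding's descriptor takes
#' exactly one categorical value -- so a rule fires at strength 1 when
#' every clause matches its input and 0 otherwise. Consequents are
#' normal, convex triangular membership functions on \[0, 100\].
#'
#' @name fuzzy_engine
NULL

.default_engine_config <- function() {
  list(structure = "mamdani", implication = "min", aggregation = "max",
       defuzzification = "centroid", resolution = 2001L)
}

#' Construct a validated expert-system specification
#'
#' @param name System name (e.g. `"masses"`).
#' @param inputs Named list: input variable -> character vector of its
#'   categories (each category is a singleton membership function).
#' @param output_name Name of the output (risk) variable.
#' @param consequents Named list of ordered consequent labels ->
#'   numeric `c(a, b, c)` triangle vertices on \[0, 100\], `a <= b <= c`,
#'   with peaks `b` strictly increasing across labels.
#' @param rules List of rules; each rule is
#'   `list(when = c(variable = "category", ...), then = "label")`.
#' @param config Inference configuration; defaults to the Mamdani
#'   MIN/MAX/centroid configuration and should normally be left alone.
#' @return An `expert_system` object.
#' @export
expert_system <- function(name, inputs, output_name, consequents, rules,
                          config = .default_engine_config()) {
  stopifnot(is.character(name), length(name) == 1)
  stopifnot(is.list(inputs), length(inputs) > 0, !is.null(names(inputs)))
  stopifnot(is.list(consequents), length(consequents) >= 2)

  cfg <- utils::modifyList(.default_engine_config(), config)
  forced <- .default_engine_config()[c("structure", "implication",
                                       "aggregation", "defuzzification")]
  for (k in names(forced)) {
    if (!identical(tolower(cfg[[k]]), forced[[k]])) {
      warning(sprintf("non-standard inference setting %s = '%s' (expected '%s')",
                      k, cfg[[k]], forced[[k]]), call. = FALSE)
    }
    cfg[[k]] <- tolower(cfg[[k]])
  }
  cfg$resolution <- as.integer(cfg$resolution)
  stopifnot(cfg$resolution >= 101L)

  for (lab in names(consequents)) {
    v <- as.numeric(consequents[[lab]])
    if (length(v) != 3 || v[1] > v[2] || v[2] > v[3] || v[1] < 0 || v[3] > 100) {
      stop(sprintf("consequent '%s' must be a triangle a <= b <= c within [0, 100]",
                   lab), call. = FALSE)
    }
    consequents[[lab]] <- v
  }
  peaks <- vapply(consequents, `[`, numeric(1), 2)
  if (any(diff(peaks) <= 0)) {
    stop("consequent label peaks must be strictly increasing", call. = FALSE)
  }

  for (i in seq_along(rules)) {
    r <- rules[[i]]
    if (is.null(r$when) || length(r$when) == 0 || is.null(names(r$when))) {
      stop(sprintf("rule %d: empty or unnamed antecedent", i), call. = FALSE)
    }
    r$when <- vapply(r$when, as.character, character(1))
    for (v in names(r$when)) {
      if (!v %in% names(inputs)) {
        stop(sprintf("rule %d: unknown input variable '%s'", i, v), call. = FALSE)
      }
      if (!r$when[[v]] %in% inputs[[v]]) {
        stop(sprintf("rule %d: unknown category '%s' for variable '%s'",
                     i, r$when[[v]], v), call. = FALSE)
      }
    }
    if (is.null(r$then) || !as.character(r$then) %in% names(consequents)) {
      stop(sprintf("rule %d: unknown consequent label '%s'", i, r$then),
           call. = FALSE)
    }
    rules[[i]] <- list(when = r$when, then = as.character(r$then))
  }

  structure(list(name = name, inputs = inputs,
                 output = list(name = output_name, labels = consequents),
                 rules = rules, config = cfg),
            class = "expert_system")
}

#' @export
print.expert_system <- function(x, ...) {
  cat(sprintf("<expert_system> %s: %d input(s), %d rule(s), output '%s' (%d labels)\n",
              x$name, length(x$inputs), length(x$rules), x$output$name,
              length(x$output$labels)))
  invisible(x)
}

#' Firing strength of one rule against singleton inputs
#'
#' With singleton antecedent membership functions the MIN over clause
#' memberships is 1 exactly when every clause's category equals the
#' input category, and 0 otherwise.
#'
#' @param rule A rule (`list(when = c(var = "cat", ...), then = "label")`).
#' @param inputs Named character vector, variable -> observed category;
#'   must cover every variable in the rule's antecedent.
#' @param spec Optional `expert_system` used to check that variables and
#'   categories exist.
#' @return Firing degree in \[0, 1\].
#' @export
firing_strength <- function(rule, inputs, spec = NULL) {
  vars <- names(rule$when)
  missing_vars <- setdiff(vars, names(inputs))
  if (length(missing_vars) > 0) {
    stop("inputs missing antecedent variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  if (!is.null(spec)) {
    for (v in vars) {
      if (!v %in% names(spec$inputs)) {
        stop(sprintf("unknown input variable '%s'", v), call. = FALSE)
      }
      if (!inputs[[v]] %in% spec$inputs[[v]]) {
        stop(sprintf("unknown category '%s' for variable '%s'", inputs[[v]], v),
             call. = FALSE)
      }
    }
  }
  # MIN over singleton clause memberships
  min(as.numeric(unname(inputs[vars]) == unname(rule$when)))
}

# triangular membership evaluated on a numeric grid; degenerate edges
# (a == b or b == c) are shoulder triangles with full membership at the peak
.tri_membership <- function(x, abc) {
  a <- abc[1]; b <- abc[2]; cc <- abc[3]
  left <- if (b > a) (x - a) / (b - a) else rep(1, length(x))
  right <- if (cc > b) (cc - x) / (cc - b) else rep(1, length(x))
  mu <- pmin(left, right)
  mu[x < a | x > cc] <- 0
  pmin(pmax(mu, 0), 1)
}

#' Aggregate fired consequents and defuzzify by centroid
#'
#' Each consequent triangle is clipped (MIN) at its firing strength, the
#' clipped sets are combined by pointwise MAX, and the centroid
#' \eqn{\int x \mu(x) dx / \int \mu(x) dx} is computed by the trapezoid
#' rule on `resolution` uniformly spaced points over \[0, 100\].
#'
#' @param spec An `expert_system`.
#' @param strengths Named numeric vector, consequent label -> firing
#'   degree in \[0, 1\]; at least one must be positive.
#' @return Crisp value in \[0, 100\].
#' @export
aggregate_and_defuzzify <- function(spec, strengths) {
  labs <- names(spec$output$labels)
  s <- stats::setNames(numeric(length(labs)), labs)
  if (length(strengths) > 0) {
    unknown <- setdiff(names(strengths), labs)
    if (length(unknown) > 0) {
      stop("unknown consequent label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    s[names(strengths)] <- strengths
  }
  if (all(s <= 0)) {
    stop("no rule fired: all consequent strengths are zero", call. = FALSE)
  }
  n <- spec$config$resolution
  x <- seq(0, 100, length.out = n)
  mu <- rep(0, n)
  for (lab in labs[s > 0]) {
    mu <- pmax(mu, pmin(s[[lab]], .tri_membership(x, spec$output$labels[[lab]])))
  }
  w <- rep(1, n); w[c(1, n)] <- 0.5  # trapezoid weights (uniform grid)
  sum(w * x * mu) / sum(w * mu)
}

#' Run full Mamdani inference for one set of categorical inputs
#'
#' Computes each rule's firing strength, takes the MAX strength per
#' consequent label (several rules may share a label), and defuzzifies.
#'
#' @param spec An `expert_system`.
#' @param inputs Named character vector, variable -> observed category.
#' @return Crisp output in \[0, 100\].
#' @export
infer <- function(spec, inputs) {
  inputs <- vapply(inputs, as.character, character(1))
  strengths <- stats::setNames(numeric(length(spec$output$labels)),
                               names(spec$output$labels))
  for (r in spec$rules) {
    fs <- firing_strength(r, inputs, spec = spec)
    if (fs > strengths[[r$then]]) strengths[[r$then]] <- fs
  }
  aggregate_and_defuzzify(spec, strengths)
}

#' Load an expert system from a YAML/JSON rule-base file
#'
#' The file declares input variables with their category lists, the
#' consequent labels as `[a, b, c]` triangle vertices, and the rule list
#' (`when:` clause map, `then:` label). The inference configuration is
#' forced to the standard Mamdani MIN/MAX/centroid settings unless the
#' file explicitly overrides them, in which case a warning is raised.
#'
#' @param path Rule-base file (`.yaml`/`.yml` or `.json`).
#' @return An `expert_system`.
#' @export
load_expert_system <- function(path) {
  if (!file.exists(path)) stop("rule-base file not found: ", path, call. = FALSE)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  for (req in c("name", "inputs", "output", "rules")) {
    if (is.null(doc[[req]])) {
      stop("rule-base file missing section '", req, "'", call. = FALSE)
    }
  }
  inputs <- lapply(doc$inputs, function(v) vapply(v, as.character, character(1)))
  consequents <- lapply(doc$output$labels, function(v) as.numeric(unlist(v)))
  rules <- lapply(doc$rules, function(r) {
    list(when = vapply(r$when, as.character, character(1)), then = r$then)
  })
  cfg <- if (!is.null(doc$config)) doc$config else list()
  expert_system(doc$name, inputs, doc$output$name, consequents, rules,
                config = utils::modifyList(.default_engine_config(), cfg))
}

#' Save an expert system to a YAML rule-base file
#'
#' `load_expert_system(save_expert_system(spec, f))` is semantically the
#' identity.
#'
#' @param spec An `expert_system`.
#' @param path Output path (`.yaml`).
#' @return The path, invisibly.
#' @export
save_expert_system <- function(spec, path) {
  doc <- list(
    name = spec$name,
    config = spec$config,
    inputs = spec$inputs,
    output = list(name = spec$output$name,
                  labels = lapply(spec$output$labels, as.numeric)),
    rules = lapply(spec$rules, function(r) {
      list(when = as.list(r$when), then = r$then)
    }))
  yaml::write_yaml(doc, path)
  invisible(path)
}
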