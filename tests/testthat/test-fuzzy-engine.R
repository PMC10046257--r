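toy_spec <- function(rules = NULL) {
  if (is.null(rules)) {
    rules <- list(
      list(when = c(shape = "irregular", margins = "spiculated"), then = "very-high"),
      list(when = c(shape = "oval", margins = "circumscribed"), then = "low"))
  }
  expert_system(
    "toy",
    inputs = list(shape = c("oval", "irregular"),
                  margins = c("circumscribed", "spiculated")),
    output_name = "risk",
    consequents = list("very-low" = c(0, 0, 25), "low" = c(0, 25, 50),
                       "medium" = c(25, 50, 75), "high" = c(50, 75, 100),
                       "very-high" = c(75, 100, 100)),
    rules = rules)
}

test_that("singleton firing strength is 1 iff every clause matches", {
  rule <- list(when = c(shape = "irregular", margins = "spiculated"),
               then = "very-high")
  expect_equal(firing_strength(rule, c(shape = "irregular", margins = "spiculated")), 1)
  expect_equal(firing_strength(rule, c(shape = "oval", margins = "spiculated")), 0)
  expect_error(firing_strength(rule, c(shape = "irregular")),
               "missing antecedent variable")
  expect_error(firing_strength(rule, c(shape = "star", margins = "spiculated"),
                               spec = toy_spec()), "unknown category")
})

test_that("centroid defuzzification matches closed-form symmetric cases", {
  spec <- toy_spec()
  expect_equal(aggregate_and_defuzzify(spec, c(medium = 1)), 50)
  expect_equal(aggregate_and_defuzzify(spec, c(high = 1)), 75)
  # mirror-symmetric aggregate of (0,25,50) and (50,75,100)
  expect_equal(aggregate_and_defuzzify(spec, c(low = 1, high = 1)), 50)
  expect_error(aggregate_and_defuzzify(spec, c(medium = 0)), "no rule fired")
  expect_error(aggregate_and_defuzzify(spec, c(ultra = 1)), "unknown consequent")
})

test_that("a clipped consequent matches the fine-grid integration oracle", {
  spec <- toy_spec()
  got <- aggregate_and_defuzzify(spec, c(high = 0.5))
  want <- oracle_defuzzify(spec$output$labels, list(high = 0.5))
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("the engine agrees with the fine-grid Mamdani oracle on random systems", {
  spec <- toy_spec()
  set.seed(424)
  for (i in 1:50) {
    s <- random_strengths()
    got <- aggregate_and_defuzzify(spec, s[s > 0])
    want <- oracle_defuzzify(spec$output$labels, as.list(s))
    expect_lt(abs(got - want), 1e-3)
  }
})

test_that("inference output is bounded and invariant under rule reordering", {
  spec <- toy_spec()
  set.seed(7)
  inputs_grid <- expand.grid(shape = spec$inputs$shape,
                             margins = spec$inputs$margins,
                             stringsAsFactors = FALSE)
  # only two input combinations are covered by the toy rules
  covered <- inputs_grid[c(1, 4), ]
  for (i in seq_len(nrow(covered))) {
    inp <- c(shape = covered$shape[i], margins = covered$margins[i])
    v <- infer(spec, inp)
    expect_gte(v, 0); expect_lte(v, 100)
    shuffled <- toy_spec(rules = rev(spec$rules))
    expect_equal(infer(shuffled, inp), v)
  }
})

test_that("an always-matching rule to the top label yields its full-strength centroid", {
  spec <- expert_system(
    "const", inputs = list(a = "x"), output_name = "r",
    consequents = list(lo = c(0, 25, 50), hi = c(50, 75, 100)),
    rules = list(list(when = c(a = "x"), then = "hi")))
  expect_equal(infer(spec, c(a = "x")), 75)
})

test_that("spec construction rejects malformed systems", {
  cons <- list(lo = c(0, 25, 50), hi = c(50, 75, 100))
  expect_error(expert_system("bad", list(a = "x"), "r", cons,
                             list(list(when = c(a = "x"), then = "ultra-high"))),
               "rule 1.*unknown consequent")
  expect_error(expert_system("bad", list(a = "x"), "r", cons,
                             list(list(when = c(b = "x"), then = "hi"))),
               "rule 1.*unknown input variable")
  expect_error(expert_system("bad", list(a = "x"), "r",
                             list(lo = c(0, 75, 100), hi = c(0, 25, 50)),
                             list(list(when = c(a = "x"), then = "hi"))),
               "strictly increasing")
  expect_error(expert_system("bad", list(a = "x"), "r",
                             list(lo = c(50, 25, 0), hi = c(50, 75, 100)),
                             list(list(when = c(a = "x"), then = "hi"))),
               "triangle")
})

test_that("rule-base files load, reject unknown labels, and round-trip", {
  spec <- load_expert_system(default_rule_base_path("masses"))
  expect_s3_class(spec, "expert_system")
  expect_identical(spec$config$implication, "min")
  expect_identical(spec$config$aggregation, "max")
  expect_identical(spec$config$defuzzification, "centroid")
  expect_length(spec$rules, 120)  # full 5 x 6 x 4 antecedent grid

  path <- tempfile(fileext = ".yaml")
  save_expert_system(spec, path)
  back <- load_expert_system(path)
  expect_equal(back, spec)

  doc <- yaml::read_yaml(path)
  doc$rules[[1]]$then <- "ultra-high"
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, bad)
  expect_error(load_expert_system(bad), "rule 1.*unknown consequent")
})

test_that("non-standard inference settings load with a warning", {
  spec <- load_expert_system(default_rule_base_path("masses"))
  doc <- yaml::read_yaml(default_rule_base_path("masses"))
  doc$config$implication <- "PROD"
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, path)
  expect_warning(load_expert_system(path), "non-standard")
})
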