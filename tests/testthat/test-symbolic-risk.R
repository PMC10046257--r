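specs <- default_expert_systems()

record_with <- function(...) {
  validate_record(utils::modifyList(list(
    patient_id = "r", age = 50, personal_history = "no",
    family_history = "none", mass_present = "absent",
    calc_present = "absent", asymmetry_present = "absent",
    distortion_present = "absent", breast_density = "fatty",
    birads = "2"), list(...)))
}

test_that("absent finding groups yield NULL risks, present ones never do", {
  rec <- record_with()
  expect_null(assess_masses(rec, specs$masses))
  expect_null(assess_calcifications(rec, specs$calcifications))
  expect_null(assess_asymmetry_distortion(rec, specs$asymmetry_distortion))

  rec2 <- record_with(mass_present = "present", mass_shape = "oval",
                      mass_margins = "circumscribed", mass_density = "low density")
  expect_true(is.numeric(assess_masses(rec2, specs$masses)))
})

test_that("the case-study pattern gives (value, value, NULL)", {
  rs <- assess_all(case_study_patient(), specs)
  expect_true(rs$R1 >= 0 && rs$R1 <= 100)
  expect_true(rs$R2 >= 0 && rs$R2 <= 100)
  expect_null(rs$R3)
})

test_that("more suspicious mass descriptors never score lower", {
  hi <- record_with(mass_present = "present", mass_shape = "irregular",
                    mass_margins = "spiculated", mass_density = "equal density")
  lo <- record_with(mass_present = "present", mass_shape = "oval",
                    mass_margins = "circumscribed", mass_density = "low density")
  expect_gte(assess_masses(hi, specs$masses), assess_masses(lo, specs$masses))

  chi <- record_with(calc_present = "present", calc_type = "primary",
                     calc_shape = "fine pleomorphic", calc_distribution = "segmental")
  clo <- record_with(calc_present = "present", calc_type = "primary",
                     calc_shape = "skin", calc_distribution = "diffuse")
  expect_gte(assess_calcifications(chi, specs$calcifications),
             assess_calcifications(clo, specs$calcifications))

  ahi <- record_with(asymmetry_present = "present", asymmetry_type = "developing",
                     distortion_present = "present", distortion_type = "associated")
  alo <- record_with(asymmetry_present = "present", asymmetry_type = "focal")
  expect_gte(assess_asymmetry_distortion(ahi, specs$asymmetry_distortion),
             assess_asymmetry_distortion(alo, specs$asymmetry_distortion))
})

test_that("the masses rule base is total and bounded over its full grid", {
  ords <- suspicion_ordinals()$masses
  grid <- expand.grid(shape = names(ords$shape), margins = names(ords$margins),
                      density = names(ords$density), stringsAsFactors = FALSE)
  expect_equal(nrow(grid), 120)
  vals <- vapply(seq_len(nrow(grid)), function(i) {
    infer(specs$masses, c(shape = grid$shape[i], margins = grid$margins[i],
                          density = grid$density[i]))
  }, numeric(1))
  expect_true(all(vals >= 0 & vals <= 100))
})

test_that("all three rule bases respond monotonically over their exhaustive grids", {
  for (sys_name in names(specs)) {
    ords <- suspicion_ordinals()[[sys_name]]
    spec <- specs[[sys_name]]
    grid <- expand.grid(lapply(ords, names), stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    key <- apply(grid, 1, paste, collapse = "|")
    vals <- vapply(seq_len(nrow(grid)), function(i) {
      infer(spec, vapply(names(ords), function(v) grid[[v]][i], character(1)))
    }, numeric(1))
    names(vals) <- key
    expect_true(all(vals >= 0 & vals <= 100), label = sys_name)
    # stepping any one variable up the suspicion ordering never lowers the output
    for (v in names(ords)) {
      ord_cats <- names(sort(ords[[v]]))
      for (ci in seq_len(length(ord_cats) - 1)) {
        from <- grid[[v]] == ord_cats[ci]
        stepped <- grid[from, , drop = FALSE]
        stepped[[v]] <- ord_cats[ci + 1]
        k2 <- apply(stepped, 1, paste, collapse = "|")
        expect_true(all(vals[k2] >= vals[key[from]] - 1e-9),
                    label = paste(sys_name, v, ord_cats[ci]))
      }
    }
  }
})

test_that("assessment order does not matter", {
  rec <- case_study_patient()
  a <- assess_all(rec, specs)
  r3 <- assess_asymmetry_distortion(rec, specs$asymmetry_distortion)
  r2 <- assess_calcifications(rec, specs$calcifications)
  r1 <- assess_masses(rec, specs$masses)
  expect_identical(a$R1, r1)
  expect_identical(a$R2, r2)
  expect_identical(a$R3, r3)
})

test_that("an uncovered input combination raises a configuration error", {
  tiny <- expert_system(
    "masses", inputs = suspicion_ordinals()$masses |> lapply(names),
    output_name = "R1",
    consequents = list(lo = c(0, 25, 50), hi = c(50, 75, 100)),
    rules = list(list(when = c(shape = "oval", margins = "circumscribed",
                               density = "none"), then = "lo")))
  rec <- record_with(mass_present = "present", mass_shape = "irregular",
                     mass_margins = "spiculated", mass_density = "high density")
  expect_error(assess_masses(rec, tiny), "does not cover.*irregular")
})
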