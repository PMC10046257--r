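#' Generate a synthetic screening cohort
#'
#' Produces a schema-conforming labeled cohort emulating the study
#' design the system was developed for: 130 screened patients of whom 21
#' have biopsy-confirmed breast cancer, mean age 55.2. Each patient
#' draws a latent liability \eqn{z \sim N(0,1)}; cancer labels go to the
#' top `n_cancer` liabilities (exact counts always), optionally degraded
#' by label-noise swaps that preserve the class counts. Finding
#' present/absent flags are liability-coupled through a logistic link,
#' and each categorical descriptor is sampled from its vocabulary with
#' probabilities tilted toward the suspicious end by
#' `liability * effect_size`, planting the monotone association between
#' suspicious descriptor values and the cancer label that the real
#' cohort exhibits. The BI-RADS category blends a liability-quantile
#' assignment with a label-informed one according to
#' `birads_informativeness`.
#'
#' The generator emulates the schema, class imbalance and mean age only;
#' it makes no attempt to match the real cohort's joint distribution.
#'
#' @param n Cohort size (default 130).
#' @param n_cancer Number of cancer labels (default 21); `0 < n_cancer < n`.
#' @param seed Integer seed; runs are bit-reproducible under it.
#' @param effect_size Strength of the liability-descriptor coupling
#'   (default 2; 0 gives a null cohort with label-independent descriptors).
#' @param birads_informativeness Probability that a patient's BI-RADS
#'   category is drawn from the label-informed distribution rather than
#'   the liability quantile map (default 0.8).
#' @param label_noise Expected fraction of cancer labels swapped with
#'   non-cancer labels (default 0).
#' @param age_mean,age_sd Age distribution, Normal truncated to (25, 95)
#'   (defaults 55.2 and 10).
#' @return A labeled [new_cohort()] whose provenance records the
#'   generator configuration.
#' @export
generate_cohort <- function(n = 130, n_cancer = 21, seed = NULL,
                            effect_size = 2, birads_informativeness = 0.8,
                            label_noise = 0, age_mean = 55.2, age_sd = 10) {
  if (!(n_cancer > 0 && n_cancer < n)) {
    stop("need 0 < n_cancer < n", call. = FALSE)
  }
  if (label_noise < 0 || label_noise >= 1 || birads_informativeness < 0 ||
      birads_informativeness > 1 || effect_size < 0 || age_sd <= 0) {
    stop("invalid generator configuration", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  voc <- record_vocabulary()
  ords <- suspicion_ordinals()

  z <- stats::rnorm(n)
  label <- rep("non-cancer", n)
  label[order(z, decreasing = TRUE)[seq_len(n_cancer)]] <- "cancer"
  if (label_noise > 0) {
    n_swap <- stats::rbinom(1, n_cancer, label_noise)
    if (n_swap > 0) {
      ci <- sample(which(label == "cancer"), n_swap)
      hi <- sample(which(label == "non-cancer"), n_swap)
      label[ci] <- "non-cancer"; label[hi] <- "cancer"
    }
  }

  # tilted categorical draw: weights exp(effect * z * ordinal / max ordinal)
  draw_cat <- function(categories, ordinals, zi) {
    o <- ordinals[categories] / max(ordinals)
    w <- exp(effect_size * zi * o)
    sample(categories, 1, prob = w / sum(w))
  }
  present <- function(base_logodds, zi) {
    stats::runif(1) < stats::plogis(base_logodds + effect_size * zi)
  }

  age <- round(pmin(pmax(stats::rnorm(n, age_mean, age_sd), 25.1), 94.9), 1)

  # BI-RADS: liability percentile mapped onto the assessment scale
  birads_scale <- c("1", "2", "3", "4A", "4B", "4C", "5")
  quantile_birads <- birads_scale[
    findInterval(stats::pnorm(z), c(0.25, 0.55, 0.75, 0.85, 0.92, 0.97)) + 1]

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    zi <- z[i]
    mass <- present(-0.3, zi)
    calc <- present(-0.7, zi)
    asym <- present(-1.8, zi)
    dist <- present(-2.0, zi)
    informed <- stats::runif(1) < birads_informativeness
    birads <- if (informed) {
      if (label[i] == "cancer") sample(c("4B", "4C", "5"), 1)
      else sample(c("1", "2", "3"), 1, prob = c(0.4, 0.4, 0.2))
    } else {
      quantile_birads[i]
    }
    rows[[i]] <- list(
      patient_id = sprintf("SYN%04d", i),
      age = age[i],
      personal_history = draw_cat(c("no", "yes"), c(no = 0, yes = 1), zi * 0.5),
      family_history = draw_cat(c("none", "minor", "major"),
                                c(none = 0, minor = 1, major = 2), zi * 0.5),
      mass_present = mass,
      mass_shape = if (mass) draw_cat(setdiff(voc$mass_shape, "none"),
                                      ords$masses$shape, zi) else "none",
      mass_margins = if (mass) draw_cat(setdiff(voc$mass_margins, "none"),
                                        ords$masses$margins, zi) else "none",
      mass_density = if (mass) draw_cat(setdiff(voc$mass_density, "none"),
                                        ords$masses$density, zi) else "none",
      calc_present = calc,
      calc_type = if (calc) draw_cat(setdiff(voc$calc_type, "none"),
                                     ords$calcifications$type, zi) else "none",
      calc_shape = if (calc) draw_cat(setdiff(voc$calc_shape, "none"),
                                      ords$calcifications$shape, zi) else "none",
      calc_distribution = if (calc) draw_cat(
        setdiff(voc$calc_distribution, "none"),
        ords$calcifications$distribution, zi) else "none",
      asymmetry_present = asym,
      asymmetry_type = if (asym) draw_cat(setdiff(voc$asymmetry_type, "none"),
                                          ords$asymmetry_distortion$asymmetry_type,
                                          zi) else "none",
      distortion_present = dist,
      distortion_type = if (dist) draw_cat(setdiff(voc$distortion_type, "none"),
                                           ords$asymmetry_distortion$distortion_type,
                                           zi) else "none",
      breast_density = draw_cat(setdiff(voc$breast_density, "missing"),
                                c("fatty" = 0, "scattered fibroglandular" = 1,
                                  "heterogeneously dense" = 2,
                                  "extremely dense" = 3), zi * 0.3),
      birads = birads,
      label = label[i])
  }

  prov <- sprintf(
    "synthetic: n=%d n_cancer=%d seed=%s effect_size=%g birads_informativeness=%g label_noise=%g age=(%g, %g)",
    n, n_cancer, if (is.null(seed)) "none" else seed, effect_size,
    birads_informativeness, label_noise, age_mean, age_sd)
  new_cohort(lapply(rows, validate_record), provenance = prov)
}

#' The published case-study patient
#'
#' A 65-year-old patient with no personal or family history of cancer:
#' an irregular, spiculated mass of homogeneous (equal) density;
#' associated coarse-heterogeneous calcifications with grouped
#' distribution; no asymmetry and no architectural distortion;
#' heterogeneously dense breast tissue; BI-RADS category 4B.
#'
#' @return A validated `patient_record` (unlabeled: this is the
#'   screening input, not a training row).
#' @export
case_study_patient <- function() {
  validate_record(list(
    patient_id = "case-study", age = 65,
    personal_history = "no", family_history = "none",
    mass_present = "present", mass_shape = "irregular",
    mass_margins = "spiculated", mass_density = "Homogeneous",
    calc_present = "present", calc_type = "associated",
    calc_shape = "coarse heterogeneous", calc_distribution = "grouped",
    asymmetry_present = "absent", distortion_present = "absent",
    breast_density = "heterogeneously dense", birads = "4B"))
}

#' Published component risks for the case-study patient
#'
#' The component risks printed for the case study: Symbolic Risks
#' R1 = 89.97 and R2 = 99.98 (R3 null, both asymmetry and distortion
#' absent) and Statistical Risk Rs = 25.61. They were produced with the
#' original authors' unpublished rule bases and trained model, so this
#' fixture lets the aggregation and correction stages be exercised
#' against the printed worked example independently of the bundled
#' default rule bases.
#'
#' @return `list(risks = list(R1 = 89.97, R2 = 99.98, R3 = NULL), Rs = 25.61)`.
#' @export
reference_risk_fixture <- function() {
  list(risks = structure(list(R1 = 89.97, R2 = 99.98, R3 = NULL),
                         class = "symbolic_risk_set"),
       Rs = 25.61)
}
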