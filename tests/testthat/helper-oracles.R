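# Independent brute-force oracles used to cross-check the package's
# numerical operations. Deliberately written with different code paths
# from the implementation (dense fine grids, exhaustive loops).

# fine-grid Mamdani centroid: clip each triangle at its strength, take
# the pointwise max, integrate numerator/denominator by the trapezoid
# rule on >= 1e5 points
oracle_defuzzify <- function(labels, strengths, npts = 200001L) {
  x <- seq(0, 100, length.out = npts)
  tri <- function(x, a, b, cc) {
    up <- if (b > a) (x - a) / (b - a) else as.numeric(x >= a)
    dn <- if (cc > b) (cc - x) / (cc - b) else as.numeric(x <= cc)
    m <- pmin(up, dn)
    m[x < a | x > cc] <- 0
    pmin(pmax(m, 0), 1)
  }
  mu <- rep(0, npts)
  for (lab in names(strengths)) {
    if (strengths[[lab]] <= 0) next
    v <- labels[[lab]]
    mu <- pmax(mu, pmin(strengths[[lab]], tri(x, v[1], v[2], v[3])))
  }
  h <- x[2] - x[1]
  trap <- function(y) h * (sum(y) - (y[1] + y[npts]) / 2)
  trap(x * mu) / trap(mu)
}

# exhaustive confusion counting by explicit loop
oracle_confusion <- function(predicted, truth) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == "cancer") {
      if (predicted[i] == "cancer") tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (predicted[i] == "cancer") fp <- fp + 1L else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

oracle_mcc <- function(tp, fp, tn, fn) {
  num <- tp * tn - fp * fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else num / den
}

# AUC by exhaustive case-control pair counting with half credit for ties
oracle_auc <- function(scores, truth) {
  pos <- which(truth == "cancer")
  neg <- which(truth == "non-cancer")
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  total / (length(pos) * length(neg))
}

# random Mamdani system over the default five-label consequent set
random_strengths <- function() {
  s <- round(stats::runif(5), 3)
  s[sample(5, sample(0:3, 1))] <- 0
  if (all(s == 0)) s[sample(5, 1)] <- round(stats::runif(1, 0.1, 1), 3)
  names(s) <- c("very-low", "low", "medium", "high", "very-high")
  s
}

# compare feature tables by their data content, ignoring bookkeeping
# attributes (labels, categorical, norm_params, synthetic)
plain_df <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "row.names", "class")]
  class(x) <- "data.frame"
  x
}
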