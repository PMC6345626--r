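## Cohort statistics: exact paired Wilcoxon signed-rank by sign
## enumeration, log-stiffness regression, responder classification,
## cohort summaries.

#' Exact paired Wilcoxon signed-rank test
#'
#' Signed-rank statistic W+ (sum of ranks of the positive differences)
#' with zero differences dropped and tied absolute differences given
#' averaged ranks. The two-sided p-value is exact: all 2^n assignments
#' of signs to the retained differences are enumerated, and the doubled
#' smaller tail probability (capped at 1) is returned. Intended for the
#' small paired samples of this design (n <= 12).
#'
#' @param x,y paired numeric vectors of equal length.
#' @return list with `statistic` (W+), `p.value`, `n_used` (non-zero
#'   differences), `ranks`.
#' @examples
#' wilcoxon_signed_rank_exact(c(2, 3, 4, 5, 6, 7), c(1, 2, 3, 4, 5, 6))
#' @export
wilcoxon_signed_rank_exact <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate test: all differences are zero")
  if (n > 20) stop("exact enumeration supports n <= 20")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ## enumerate all 2^n sign assignments
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wdist <- as.vector(signs %*% r)
  p_lo <- mean(Wdist <= W + 1e-9)
  p_hi <- mean(Wdist >= W - 1e-9)
  p <- min(1, 2 * min(p_lo, p_hi))
  list(statistic = W, p.value = p, n_used = n, ranks = r)
}

#' Pair two designs' ingrowth values across the cohort
#'
#' Between-design comparisons use n = 6 values per design, but a design
#' pair co-occurs within the same animal only in a subset of the
#' cohort. Values from co-occurring animals are paired within animal;
#' the remaining values of each design are paired by rank order.
#'
#' @param table cohort results (columns animal, design, fraction).
#' @param design_a,design_b design acronyms.
#' @return list with `x`, `y` (paired vectors, design_a first) and
#'   `n_within` (within-animal pairs).
#' @export
pair_design_values <- function(table, design_a, design_b) {
  ta <- table[table$design == design_a, ]
  tb <- table[table$design == design_b, ]
  shared <- intersect(ta$animal, tb$animal)
  x <- ta$fraction[match(shared, ta$animal)]
  y <- tb$fraction[match(shared, tb$animal)]
  rest_a <- sort(ta$fraction[!ta$animal %in% shared])
  rest_b <- sort(tb$fraction[!tb$animal %in% shared])
  stopifnot(length(rest_a) == length(rest_b))
  list(x = c(x, rest_a), y = c(y, rest_b), n_within = length(shared))
}

#' All pairwise between-design Wilcoxon tests
#'
#' Runs the exact signed-rank test for each of the six design pairs,
#' using within-animal pairing where available and rank-order pairing
#' for the remainder (reported in `n_within`). P-values are unadjusted
#' by default; `holm = TRUE` applies a Holm correction.
#'
#' @param table cohort results (animal, design, fraction).
#' @param holm apply Holm adjustment (default FALSE).
#' @return data frame: design_a, design_b, statistic, p, n_within.
#' @export
design_pairwise_tests <- function(table, holm = FALSE) {
  des <- c("TC", "TB", "PB", "PC")
  out <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    pr <- pair_design_values(table, des[i], des[j])
    ts <- wilcoxon_signed_rank_exact(pr$x, pr$y)
    out[[length(out) + 1L]] <- data.frame(
      design_a = des[i], design_b = des[j], statistic = ts$statistic,
      p = ts$p.value, n_within = pr$n_within)
  }
  out <- do.call(rbind, out)
  if (holm) out$p <- stats::p.adjust(out$p, "holm")
  out
}

#' Regression of ingrowth on log scaffold stiffness
#'
#' Ordinary least squares of the ingrowth fraction (percent of pore
#' volume) on log10 of the apparent modulus (MPa); the stiffness scale
#' of the four designs is exponential, spanning roughly 200 to 7000
#' MPa, hence the log transform. Returns the slope (expected negative:
#' stiffer scaffolds accrue less bone), r-squared and the slope
#' p-value.
#'
#' @param table cohort results with columns `fraction` and `modulus`.
#' @return list with `slope`, `r_squared`, `p.value`, `n`.
#' @export
stiffness_regression <- function(table) {
  if (nrow(table) < 3) stop("regression needs at least 3 rows")
  if (any(table$modulus <= 0)) stop("moduli must be positive")
  if (length(unique(table$modulus)) < 2)
    stop("regression error: constant covariate")
  fit <- lm(fraction ~ log10(modulus), data = table)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), r_squared = sm$r.squared,
       p.value = sm$coefficients[2, 4], n = nrow(table))
}

#' Classify strong and weak responders
#'
#' Computes each animal's paired ingrowth difference (more compliant
#' scaffold minus stiffer scaffold, compliance ranked by
#' direction-averaged modulus) and splits the twelve differences into
#' two clusters by one-dimensional two-means initialized at the extreme
#' values; the upper cluster is labelled strong.
#'
#' @param table cohort results (animal, design, fraction), two rows per
#'   animal with distinct designs.
#' @return data frame: animal, difference (pp), responder_class;
#'   attribute `centers` holds the cluster centres.
#' @export
classify_responders <- function(table) {
  animals <- sort(unique(table$animal))
  diffs <- vapply(animals, function(a) {
    rows <- table[table$animal == a, ]
    if (nrow(rows) != 2) stop("each animal needs exactly 2 rows")
    ranks <- design_compliance_rank(rows$design)
    if (ranks[1] == ranks[2]) stop("animal with two identical designs")
    rows$fraction[which.min(ranks)] - rows$fraction[which.max(ranks)]
  }, numeric(1))
  if (max(diffs) - min(diffs) < 1e-9) {
    warning("single-cluster warning: identical differences across animals")
    out <- data.frame(animal = animals, difference = diffs,
                      responder_class = "strong",
                      stringsAsFactors = FALSE)
    attr(out, "centers") <- c(mean(diffs), mean(diffs))
    return(out)
  }
  km <- kmeans(diffs, centers = matrix(c(min(diffs), max(diffs))),
               algorithm = "Lloyd", iter.max = 100)
  upper <- which.max(km$centers)
  out <- data.frame(animal = animals, difference = diffs,
                    responder_class = ifelse(km$cluster == upper,
                                             "strong", "weak"),
                    stringsAsFactors = FALSE)
  attr(out, "centers") <- sort(as.vector(km$centers))
  out
}

#' Cohort summary statistics
#'
#' Group mean paired differences for strong and weak responders, the
#' overall ingrowth range, and per-design means, reported to 1 decimal.
#'
#' @param table cohort results (animal, design, fraction).
#' @param labels output of [classify_responders()]; computed if absent.
#' @return list with `strong_mean_diff`, `weak_mean_diff`, `n_strong`,
#'   `n_weak`, `min_fraction`, `max_fraction`, `design_means`.
#' @export
summarize_cohort <- function(table, labels = NULL) {
  if (is.null(labels)) labels <- classify_responders(table)
  if (!nrow(labels)) stop("empty label set")
  strong <- labels$difference[labels$responder_class == "strong"]
  weak <- labels$difference[labels$responder_class == "weak"]
  dm <- tapply(table$fraction, table$design, mean)
  list(strong_mean_diff = round(mean(strong), 1),
       weak_mean_diff = if (length(weak)) round(mean(weak), 1) else NA_real_,
       n_strong = length(strong), n_weak = length(weak),
       min_fraction = round(min(table$fraction), 1),
       max_fraction = round(max(table$fraction), 1),
       design_means = round(dm, 1))
}
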