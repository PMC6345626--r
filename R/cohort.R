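## Synthetic ovine cohort: allocation, latent osteogenic truth.

## Fixture allocation: 12 animals x 2 legs, each design used exactly 6x,
## both scaffolds of an animal distinct.
default_allocation_table <- function() {
  data.frame(
    animal = 1:12,
    left  = c("TC", "TC", "TB", "PB", "TB", "TC", "TB", "TC", "TB", "PB",
              "TC", "TC"),
    right = c("PC", "TB", "PB", "PC", "PC", "PB", "PC", "PC", "PB", "PC",
              "PB", "TB"),
    stringsAsFactors = FALSE)
}

#' Default synthetic cohort
#'
#' Generates the latent truth for the 12-animal paired study: a fixed
#' scaffold allocation (each of TC, TB, PB, PC used six times, two
#' different scaffolds per animal), a responder class per animal
#' (strong: animals 1, 5-9 and 11; weak: 2-4, 10 and 12), a common
#' injury-driven peripheral ingrowth baseline B (percent of pore
#' volume), and a strain-driven paired central gain d awarded to the
#' more compliant scaffold of each pair (compliance ranked by
#' direction-averaged modulus: PC < PB < TB < TC). Defaults encode the
#' study-level summaries: B = 6.8 pp for every animal; strong-responder
#' gains average 14.0 pp, weak-responder gains average 3.0 pp, with
#' exactly one animal (animal 4) reversed (d < 0, i.e. more ingrowth in
#' the stiffer scaffold); the largest latent total is 21 percent of
#' pore volume.
#'
#' @param seed integer seed (weights and optional jitter).
#' @param jitter_sd Gaussian jitter (pp) added independently to each
#'   animal's B and d; 0.2 by default, set 0 for the exact summaries.
#' @return list with `animals` (data frame: animal, weight_kg,
#'   responder_class, B, d), `allocation` (animal, left, right) and
#'   `truth` (one row per implanted scaffold: animal, leg, design,
#'   responder_class, compliant, peripheral_pp, latent_total_pp).
#' @export
default_cohort <- function(seed = 1L, jitter_sd = 0.2) {
  strong <- c(1, 5, 6, 7, 8, 9, 11)
  d_strong <- c(13.8, 13.9, 14.0, 14.0, 14.0, 14.1, 14.2)
  weak <- c(2, 3, 4, 10, 12)
  d_weak <- c(3.8, 3.7, -0.5, 3.9, 4.1)  # the reversed animal is 4
  d <- numeric(12)
  d[strong] <- d_strong
  d[weak] <- d_weak
  B <- rep(6.8, 12)
  cls <- ifelse(seq_len(12) %in% strong, "strong", "weak")
  alloc <- default_allocation_table()
  with_seed(child_seed(seed, "cohort"), {
    w <- numeric(12)
    for (i in 1:12) {
      repeat {
        wi <- rnorm(1, 72.8, 5.7)
        if (wi >= 62 && wi <= 85) break
      }
      w[i] <- wi
    }
    if (jitter_sd > 0) {
      B <- B + rnorm(12, 0, jitter_sd)
      d <- d + rnorm(12, 0, jitter_sd)
    }
    animals <- data.frame(animal = 1:12, weight_kg = w,
                          responder_class = cls, B = B, d = d,
                          stringsAsFactors = FALSE)
    rows <- lapply(1:12, function(i) {
      designs <- c(alloc$left[i], alloc$right[i])
      ranks <- design_compliance_rank(designs)
      compliant <- ranks == min(ranks)
      data.frame(animal = i, leg = c("L", "R"), design = designs,
                 responder_class = cls[i], compliant = compliant,
                 peripheral_pp = B[i],
                 latent_total_pp = B[i] + ifelse(compliant, d[i], 0),
                 stringsAsFactors = FALSE)
    })
    truth <- do.call(rbind, rows)
    list(animals = animals, allocation = alloc, truth = truth)
  })
}

#' Simulate independent raters for ordinal scores
#'
#' Each simulated rater reports the true score perturbed by discrete
#' noise in \{-1, 0, +1\} (probability `p_err` for each of -1 and +1),
#' clipped to the 0-4 scale.
#'
#' @param true_scores data frame with columns `sample`, `depth_mm` and
#'   one or more score columns (values in 0..4), or a numeric vector.
#' @param n_raters number of raters (default 3).
#' @param p_err probability of a +1 error and of a -1 error (default
#'   0.1 each).
#' @param seed integer seed.
#' @return the input replicated per rater with a `rater` column and
#'   perturbed scores.
#' @export
simulate_raters <- function(true_scores, n_raters = 3, p_err = 0.1,
                            seed = 1L) {
  if (is.numeric(true_scores))
    true_scores <- data.frame(score = true_scores)
  stopifnot(p_err >= 0, p_err <= 0.5)
  score_cols <- names(true_scores)[vapply(true_scores, is.numeric, TRUE)]
  score_cols <- setdiff(score_cols, c("sample", "depth_mm", "animal"))
  for (sc in score_cols)
    if (any(true_scores[[sc]] < 0 | true_scores[[sc]] > 4))
      stop("true scores must lie in 0..4")
  with_seed(child_seed(seed, "raters"), {
    out <- do.call(rbind, lapply(seq_len(n_raters), function(r) {
      df <- true_scores
      df$rater <- r
      for (sc in score_cols) {
        n <- nrow(df)
        eps <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
                      prob = c(p_err, 1 - 2 * p_err, p_err))
        df[[sc]] <- pmin(4L, pmax(0L, as.integer(round(df[[sc]])) + eps))
      }
      df
    }))
    rownames(out) <- NULL
    out
  })
}
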