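test_that("allocation uses each design six times, two distinct per animal", {
  co <- default_cohort(seed = 1)
  tr <- co$truth
  expect_equal(nrow(tr), 24)
  expect_true(all(table(tr$design) == 6))
  byA <- split(tr$design, tr$animal)
  expect_true(all(vapply(byA, function(d) length(unique(d)) == 2, TRUE)))
})

test_that("latent defaults reproduce the responder-group summaries exactly", {
  co <- default_cohort(seed = 1, jitter_sd = 0)
  an <- co$animals
  expect_equal(sort(an$animal[an$responder_class == "strong"]),
               c(1, 5, 6, 7, 8, 9, 11))
  expect_equal(mean(an$d[an$responder_class == "strong"]), 14.0)
  expect_equal(mean(an$d[an$responder_class == "weak"]), 3.0)
  ## exactly one reversed animal, and it is animal 4
  expect_equal(an$animal[an$d < 0], 4)
  ## largest latent total is 21 percent of pore volume
  expect_equal(max(co$truth$latent_total_pp), 21.0)
  ## baseline peripheral equal across animals
  expect_true(all(an$B == 6.8))
  ## compliant scaffold of each pair carries the gain
  tr <- co$truth
  for (a in 1:12) {
    rows <- tr[tr$animal == a, ]
    expect_equal(rows$latent_total_pp[rows$compliant],
                 an$B[a] + an$d[a])
    expect_equal(rows$latent_total_pp[!rows$compliant], an$B[a])
  }
})

test_that("weights stay within the documented envelope and reproduce", {
  co1 <- default_cohort(seed = 7)
  expect_true(all(co1$animals$weight_kg >= 62 & co1$animals$weight_kg <= 85))
  co2 <- default_cohort(seed = 7)
  expect_identical(co1, co2)
  expect_false(identical(co1$animals$weight_kg,
                         default_cohort(seed = 8)$animals$weight_kg))
})

test_that("rater simulation respects support and zero-noise identity", {
  truth <- data.frame(sample = rep("s", 10), depth_mm = 1:10,
                      interface = rep(2L, 10), interior = rep(3L, 10))
  r0 <- simulate_raters(truth, p_err = 0, seed = 1)
  expect_true(all(r0$interface == 2L), all(r0$interior == 3L))
  r <- simulate_raters(truth, p_err = 0.2, seed = 1)
  expect_true(all(abs(r$interface - 2) <= 1))
  expect_true(all(r$interface >= 0 & r$interface <= 4))
})

test_that("rater discrepancy beyond one unit occurs at the closed-form rate", {
  ## for truth in mid-range and p(+1) = p(-1) = 0.2 per rater:
  ## P(max - min > 1) = P(at least one +1 AND at least one -1)
  ##                  = 1 - 2*(0.8)^3 + (0.6)^3 = 0.192
  n <- 4000
  truth <- data.frame(sample = seq_len(n), depth_mm = 1, score = 2L)
  r <- simulate_raters(truth, p_err = 0.2, seed = 5)
  spread <- tapply(r$score, r$sample, function(v) max(v) - min(v))
  phat <- mean(spread > 1)
  p <- 1 - 2 * 0.8^3 + 0.6^3
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(phat - p), 4 * se)
})
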