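test_that("all-positive differences with n = 6 give the exact p = 2/64", {
  out <- wilcoxon_signed_rank_exact(c(2, 3, 4, 5, 6, 7.5),
                                    c(1, 2.5, 3, 4.2, 5, 7))
  expect_equal(out$statistic, 21)
  expect_equal(out$p.value, 0.03125)
})

test_that("identical samples raise a degenerate-test error", {
  expect_error(wilcoxon_signed_rank_exact(1:6, 1:6), "degenerate")
})

test_that("enumeration agrees with an independent oracle on random inputs", {
  set.seed(31)
  for (k in 1:40) {
    n <- sample(3:10, 1)
    x <- round(rnorm(n), 1)
    y <- round(rnorm(n), 1)
    ## occasionally force ties and zero differences
    if (k %% 4 == 0) y[1] <- x[1]
    if (k %% 5 == 0 && n > 3) y[2:3] <- x[2:3] - 0.1
    if (all(x == y)) next
    got <- wilcoxon_signed_rank_exact(x, y)
    want <- wilcoxon_oracle(x, y)
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$p.value, want$p.value)
  }
})

test_that("tie-free cases agree with the reference implementation in stats", {
  set.seed(77)
  for (k in 1:10) {
    n <- sample(5:10, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- wilcoxon_signed_rank_exact(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("collinear points give r-squared one; guards fire", {
  tab <- data.frame(fraction = c(2, 4, 6), modulus = c(10, 100, 1000))
  out <- suppressWarnings(stiffness_regression(tab))
  expect_equal(out$r_squared, 1, tolerance = 1e-12)
  expect_error(stiffness_regression(data.frame(fraction = 1:3,
                                               modulus = c(5, 5, 5))),
               "constant covariate")
  ## r-squared invariant to covariate rescaling (log-base change)
  tab2 <- data.frame(fraction = rnorm(10, 10), modulus = 10^runif(10, 1, 4))
  r1 <- stiffness_regression(tab2)$r_squared
  tab2$modulus <- tab2$modulus^2  # log10 -> doubled scale
  expect_equal(stiffness_regression(tab2)$r_squared, r1, tolerance = 1e-12)
})

test_that("permuted covariates give the null expectation of r-squared", {
  set.seed(5)
  n <- 12
  frac <- rnorm(n, 10, 3)
  mods <- 10^runif(n, 2, 4)
  r2 <- vapply(1:200, function(k) {
    stiffness_regression(data.frame(fraction = frac,
                                    modulus = sample(mods)))$r_squared
  }, numeric(1))
  ## E[r2] under the null is 1/(n-1)
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 4 * se)
})

test_that("responder classification recovers the latent split and is stable", {
  co <- default_cohort(seed = 1, jitter_sd = 0)
  tab <- data.frame(animal = co$truth$animal, design = co$truth$design,
                    fraction = co$truth$latent_total_pp)
  cls <- classify_responders(tab)
  truth_cls <- co$animals$responder_class[match(cls$animal,
                                                co$animals$animal)]
  expect_identical(cls$responder_class, truth_cls)
  expect_equal(sum(cls$responder_class == "strong"), 7)
  ## invariant to row order
  cls2 <- classify_responders(tab[sample(nrow(tab)), ])
  expect_identical(cls2$responder_class, cls$responder_class)
  ## truth recovery under 20 seeds of measurement noise
  set.seed(99)
  ok <- vapply(1:20, function(k) {
    tabn <- tab
    tabn$fraction <- tabn$fraction + rnorm(24, 0, 0.3)
    identical(classify_responders(tabn)$responder_class, truth_cls)
  }, logical(1))
  expect_true(all(ok))
})

test_that("identical differences collapse to one cluster with a warning", {
  co <- default_cohort(seed = 1, jitter_sd = 0)
  tab <- data.frame(animal = co$truth$animal, design = co$truth$design,
                    fraction = ifelse(co$truth$compliant, 10, 5))
  expect_warning(cls <- classify_responders(tab), "single-cluster")
  expect_equal(length(unique(cls$responder_class)), 1)
})

test_that("cohort summaries report the latent group means", {
  co <- default_cohort(seed = 1, jitter_sd = 0)
  tab <- data.frame(animal = co$truth$animal, design = co$truth$design,
                    fraction = co$truth$latent_total_pp)
  sm <- summarize_cohort(tab)
  expect_equal(sm$strong_mean_diff, 14.0)
  expect_equal(sm$weak_mean_diff, 3.0)
  expect_equal(sm$n_strong, 7); expect_equal(sm$n_weak, 5)
  expect_equal(sm$max_fraction, 21.0)
  expect_error(summarize_cohort(tab, labels = data.frame()), "empty")
})

test_that("design pairing uses within-animal pairs plus rank order", {
  co <- default_cohort(seed = 1, jitter_sd = 0)
  tab <- data.frame(animal = co$truth$animal, design = co$truth$design,
                    fraction = co$truth$latent_total_pp)
  pr <- pair_design_values(tab, "TC", "TB")
  expect_length(pr$x, 6)
  expect_length(pr$y, 6)
  expect_equal(pr$n_within, 2)  # TC and TB share animals 2 and 12
  tests <- design_pairwise_tests(tab)
  expect_equal(nrow(tests), 6)
  expect_true(all(tests$p >= 0 & tests$p <= 1))
})
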