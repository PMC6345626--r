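## Stress-strain curves from quasi-static compression with an
## unload-reload hysteresis loop, and modulus extraction by regression.

#' Simulate a compression stress-strain curve with a hysteresis loop
#'
#' Emulates the quasi-static compression protocol used for porous
#' specimens: initial loading to 70 percent of the estimated yield
#' strength along a "toe" of reduced slope (localized plasticity at
#' strut contacts), an unload to 20 percent of yield and a reload at the
#' true elastic modulus, then continued loading. The hysteresis branch
#' carries the elastic modulus; the toe deliberately does not.
#'
#' @param modulus true elastic modulus, MPa.
#' @param yield_strength estimated yield strength, MPa.
#' @param toe_factor slope of the initial loading toe relative to
#'   `modulus` (default 0.6).
#' @param n_per_branch samples per branch.
#' @param noise_sd additive stress noise, MPa (default 0).
#' @param seed seed for the noise.
#' @return A `stress_strain_curve`: strain, stress, `yield_estimate`,
#'   and the index range of the hysteresis branch in `branch_truth`.
#' @export
simulate_compression_curve <- function(modulus, yield_strength,
                                       toe_factor = 0.6,
                                       n_per_branch = 60, noise_sd = 0,
                                       seed = 1L) {
  s_hi <- 0.7 * yield_strength
  s_lo <- 0.2 * yield_strength
  ## toe: load 0 -> 0.7 Y at reduced slope
  stress1 <- seq(0, s_hi, length.out = n_per_branch)
  strain1 <- stress1 / (toe_factor * modulus)
  e_top <- strain1[n_per_branch]
  ## unload 0.7 Y -> 0.2 Y at the true modulus
  stress2 <- seq(s_hi, s_lo, length.out = n_per_branch)[-1]
  strain2 <- e_top - (s_hi - stress2) / modulus
  ## reload 0.2 Y -> 0.7 Y along the same elastic line
  stress3 <- seq(s_lo, s_hi, length.out = n_per_branch)[-1]
  strain3 <- strain2[length(strain2)] + (stress3 - s_lo) / modulus
  ## post-loop loading continues at the toe slope toward yield
  stress4 <- seq(s_hi, yield_strength, length.out = n_per_branch)[-1]
  strain4 <- strain3[length(strain3)] + (stress4 - s_hi) / (toe_factor * modulus)
  strain <- c(strain1, strain2, strain3, strain4)
  stress <- c(stress1, stress2, stress3, stress4)
  if (noise_sd > 0)
    stress <- stress + with_seed(seed, rnorm(length(stress), 0, noise_sd))
  loop_idx <- c(n_per_branch + 1L, n_per_branch + 2L * (n_per_branch - 1L))
  structure(list(strain = strain, stress = stress,
                 yield_estimate = yield_strength,
                 branch_truth = loop_idx),
            class = "stress_strain_curve")
}

#' Elastic modulus from the hysteresis loop of a compression curve
#'
#' Ordinary least-squares slope of stress on strain restricted to the
#' unload-reload (hysteresis) branch of the curve, within the stress
#' window expressed as fractions of the estimated yield strength. The
#' branch is located as the excursion between the first local stress
#' maximum and the sample where the stress next re-attains that level.
#'
#' @param curve a `stress_strain_curve` (fields strain, stress,
#'   yield_estimate).
#' @param window stress window as fractions of yield (default
#'   `c(0.2, 0.7)`).
#' @return modulus estimate, MPa.
#' @export
modulus_from_hysteresis <- function(curve, window = c(0.2, 0.7)) {
  stress <- curve$stress
  strain <- curve$strain
  stopifnot(length(stress) == length(strain))
  y <- curve$yield_estimate
  ## top of the initial loading branch: the first point followed by a
  ## sustained decrease (3 consecutive falling steps of the smoothed
  ## curve, so measurement noise cannot fake an unload)
  sm <- stats::filter(stress, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- stress[is.na(sm)]
  dec <- diff(sm) < 0
  runs <- dec & c(dec[-1], FALSE) & c(dec[-(1:2)], FALSE, FALSE)
  if (!any(runs)) stop("window error: curve has no unload-reload branch")
  i0 <- which(runs)[1]
  ## end of the loop: stress re-attains the branch-top level after
  ## passing through the unload minimum (smoothed, for noise immunity)
  jmin <- i0 - 1L + which.min(sm[i0:length(sm)])
  after <- seq(min(jmin + 1L, length(stress)), length(stress))
  re <- after[sm[after] >= sm[i0] - 1e-9 * max(abs(stress))]
  i1 <- if (length(re)) re[1] else length(stress)
  idx <- i0:i1
  lo <- min(window) * y; hi <- max(window) * y
  sel <- idx[stress[idx] >= lo - 1e-9 & stress[idx] <= hi + 1e-9]
  if (length(sel) < 3)
    stop("window error: hysteresis branch does not span the stress window")
  fit <- lm(stress[sel] ~ strain[sel])
  unname(coef(fit)[2])
}
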