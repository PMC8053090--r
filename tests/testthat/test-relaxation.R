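# Poisson zero-class estimation from plasmid topoisomer bands.

test_that("supercoiled_fraction is the supercoiled share of the monomer signal", {
  expect_equal(supercoiled_fraction(800, 200), 0.8)
  expect_equal(supercoiled_fraction(0, 500), 0)
  expect_equal(supercoiled_fraction(500, 0), 1)
  # scale invariance: a gain change does not move the fraction
  expect_equal(supercoiled_fraction(800 * 7, 200 * 7), 0.8)
  expect_error(supercoiled_fraction(0, 0), "zero total")
})

test_that("mean_nicks applies the zero-class formula with clamping and saturation", {
  expect_equal(mean_nicks(0.5, 0.5), 0)
  expect_equal(mean_nicks(exp(-1) * 0.9, 0.9), 1)
  expect_warning(out <- mean_nicks(0.95, 0.9), "clamped")
  expect_equal(out, 0)
  expect_warning(out <- mean_nicks(0, 0.9), "saturated")
  expect_equal(out, Inf)
})

test_that("zero-class estimate recovers the Poisson mean (brute-force oracle)", {
  # oracle: nick plasmids directly from a Poisson and read off the zero class
  withr::with_seed(42, {
    for (lambda in c(0.1, 0.7, 1.5, 3)) {
      n <- 1e5
      nicks <- rpois(n, lambda)
      f_treated <- mean(nicks == 0)
      est <- mean_nicks(f_treated, 1)
      se <- sqrt((1 - f_treated) / (n * f_treated))  # delta method on -log F
      expect_lt(abs(est - lambda), 3 * se + 1e-12)
    }
  })
})

test_that("lesions_per_genome scales nick density to the genome", {
  expect_equal(lesions_per_genome(0, 9200), 0)
  expect_equal(lesions_per_genome(1.5, 9200, 9.2e6), 1500)
  expect_error(lesions_per_genome(1, 0), "plasmid_length_nt")
})

test_that("estimator is consistent over replicate synthetic gels", {
  # property: over 200 replicates at several lambdas the pooled estimate
  # stays within 3 standard errors of the truth (direct Poisson oracle)
  withr::with_seed(7, {
    for (lambda in c(0.1, 1, 3)) {
      ests <- replicate(200, {
        nicks <- rpois(2000, lambda)
        mean_nicks(mean(nicks == 0), 1)
      })
      expect_lt(abs(mean(ests) - lambda),
                3 * stats::sd(ests) / sqrt(length(ests)))
    }
  })
})

test_that("full pipeline recovers the lesion burden from band tables", {
  sc <- scenario_preset("rnhAB")
  bt <- simulate_relaxation_series(sc, timepoints = c(-1, 5),
                                   n_replicates = 5, seed = 7)
  est <- suppressWarnings(estimate_lesion_density(bt, plasmid_length_nt = 9200))
  at5 <- est$lesions_per_genome[est$time_min == 5]
  expect_lt(abs(at5 - 36 * 41.7) / (36 * 41.7), 0.10)
  # band intensities are only ratios: scaling a lane leaves estimates alone
  bt2 <- dplyr::mutate(bt, sc_signal = sc_signal * 3.7,
                       rc_signal = rc_signal * 3.7)
  est2 <- suppressWarnings(estimate_lesion_density(bt2, plasmid_length_nt = 9200))
  expect_equal(est2$lesions_per_genome, est$lesions_per_genome)
})

test_that("percent_remaining anchors at the reference and subtracts background", {
  flat <- tibble::tibble(time_min = c(-1, 5, 30, 60),
                         lesions_per_genome = c(0, 100, 100, 100))
  pr <- percent_remaining(flat)
  expect_equal(pr$percent_remaining[pr$time_min %in% c(5, 30, 60)],
               c(100, 100, 100))
  withbg <- tibble::tibble(time_min = c(-1, 5, 30),
                           lesions_per_genome = c(40, 140, 90))
  pr2 <- percent_remaining(withbg)
  expect_equal(pr2$percent_remaining[pr2$time_min == 30], 50)
  expect_error(percent_remaining(flat, reference_timepoint = 99), "missing")
})

test_that("removal kinetics match the strain scenarios (plasmid assay)", {
  est_for <- function(preset) {
    bt <- simulate_relaxation_series(scenario_preset(preset),
                                     timepoints = c(-1, 5, 20, 60),
                                     n_replicates = 4, seed = 21)
    percent_remaining(suppressWarnings(
      estimate_lesion_density(bt, plasmid_length_nt = 9200)
    ))
  }
  wt <- est_for("WT")
  expect_lt(wt$percent_remaining[wt$time_min == 20], 60)   # about half gone
  expect_lt(wt$percent_remaining[wt$time_min == 60], 15)   # almost all gone
  ua <- est_for("uvrA")
  expect_gt(ua$percent_remaining[ua$time_min == 60], 85)   # no removal
})
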