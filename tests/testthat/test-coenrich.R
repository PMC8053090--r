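# Lane partitioning and the 16-fraction co-enrichment statistic.

with_part_attrs <- function(df) {
  attr(df, "span") <- c(0, 1)
  attr(df, "n") <- nrow(df)
  df
}

density_series <- function(values) {
  with_part_attrs(tibble::tibble(fraction = seq_along(values),
                                 density = values))
}

ratio_series <- function(values) {
  with_part_attrs(tibble::tibble(fraction = seq_along(values),
                                 ratio = values))
}

test_that("partition_lane splits the well-to-cutoff span into equal windows", {
  prof <- uniform_profile()
  fs <- partition_lane(prof)
  expect_equal(nrow(fs), 16)
  expect_equal(fs$signal, rep(1 / 16, 16), tolerance = 1e-9)
  # the fractions jointly carry the full integral over the span
  expect_equal(sum(fs$signal), 1, tolerance = 1e-9)

  # all signal within the first sixteenth lands in fraction 1
  spike <- uniform_profile()
  spike$signal <- ifelse(spike$position <= 1 / 16, 1, 0)
  fs2 <- partition_lane(spike)
  expect_gt(fs2$signal[1] / sum(fs2$signal), 0.97)

  shallow <- tibble::tibble(position = seq(0, 0.5, length.out = 64), signal = 1)
  expect_error(partition_lane(shallow), "outside")
  expect_error(partition_lane(uniform_profile(10)), "32 samples")
})

test_that("fraction densities divide western by Southern with missing flags", {
  w <- partition_lane(uniform_profile(value = 2))
  s <- partition_lane(uniform_profile(value = 1))
  expect_equal(fraction_densities(w, s)$density, rep(2, 16))
  expect_equal(fraction_densities(w, w)$density, rep(1, 16))
  s3 <- s; s3$signal <- s3$signal * 4
  expect_equal(fraction_densities(w, s3)$density, rep(0.5, 16))
  s0 <- s; s0$signal[7] <- 0
  d <- fraction_densities(w, s0)
  expect_true(is.na(d$density[7]))
  expect_false(anyNA(d$density[-7]))
  mismatch <- partition_lane(uniform_profile(), n = 8)
  expect_error(fraction_densities(w, mismatch), "partitions")
})

test_that("normalize_fractions ratios densities and propagates missing", {
  a <- density_series(rep(2, 16))
  expect_equal(normalize_fractions(a, a)$ratio, rep(1, 16))
  b <- density_series(c(rep(2, 5), 6, rep(2, 10)))
  expect_equal(normalize_fractions(b, a)$ratio,
               c(rep(1, 5), 3, rep(1, 10)))
  z <- density_series(c(0, rep(2, 15)))
  expect_warning(out <- normalize_fractions(b, z), "Zero reference")
  expect_true(is.na(out$ratio[1]))
})

test_that("co-enrichment is the product of the two normalized densities", {
  rdh <- ratio_series(c(rep(1, 5), 14.5, rep(1, 10)))
  pd <- ratio_series(c(rep(1, 5), 2, rep(1, 10)))
  co <- coenrichment_profile(rdh, pd)
  expect_equal(co$peak_fraction, 6)
  expect_equal(co$peak_value, 29)
  expect_equal(co$non_peak_mean, 1)

  ones <- ratio_series(rep(1, 16))
  expect_warning(flat <- coenrichment_profile(ones, ones), "Tied peak")
  expect_equal(flat$profile$coenrichment, rep(1, 16))
  expect_equal(flat$peak_fraction, 1)  # lowest index wins ties

  # a fraction missing in either input is missing in the product
  miss <- ratio_series(c(NA, rep(1, 15)))
  co2 <- suppressWarnings(coenrichment_profile(miss, ones))
  expect_true(is.na(co2$profile$coenrichment[1]))
  expect_equal(co2$non_peak_mean, 1)
})

test_that("permuting fraction labels permutes the co-enrichment identically", {
  withr::with_seed(3, {
    r1 <- runif(16, 0.5, 3); r2 <- runif(16, 0.5, 3)
    perm <- sample(16)
    co <- coenrichment_profile(ratio_series(r1), ratio_series(r2))
    cop <- coenrichment_profile(ratio_series(r1[perm]), ratio_series(r2[perm]))
    expect_equal(cop$profile$coenrichment,
                 co$profile$coenrichment[perm])
  })
})

test_that("fraction size map brackets the study's landmarks", {
  fmap <- fraction_size_map()
  expect_lte(fmap$size_lo_kb[6], 8)
  expect_gte(fmap$size_hi_kb[6], 10)
  expect_lte(fmap$size_lo_kb[16], 0.5)
  widths <- fmap$size_hi_kb - fmap$size_lo_kb
  expect_true(all(diff(widths) < 0))  # intervals shrink down the lane
  expect_true(all(fmap$size_lo_kb[-16] == fmap$size_hi_kb[-1]))
})

test_that("a 9-kb band integrates into fraction 6 under the default migration", {
  frags <- tibble::tibble(length = rep(9000, 200), pd_count = 0, rdh_nt = 0)
  prof <- render_lane(frags, "southern", noise_cv = 0, seed = 1)
  fs <- partition_lane(prof)
  expect_equal(which.max(fs$signal), 6)
})

test_that("identical lanes across timepoints give a co-enrichment of exactly 1", {
  prof <- uniform_profile()
  prof$signal <- 1 + sin(prof$position * 9)^2
  lanes <- tidyr::expand_grid(timepoint = c(-1, 5, 30),
                              channel = c("southern", "s96", "pd")) |>
    dplyr::rowwise() |>
    dplyr::reframe(dplyr::mutate(prof, timepoint = timepoint,
                                 channel = channel))
  expect_warning(co <- coenrichment_from_lanes(lanes), "Tied peak")
  expect_equal(co$profile$coenrichment, rep(1, 16), tolerance = 1e-12)
})

test_that("the rnhAB scenario out-contrasts the WT scenario (recovery)", {
  run <- function(preset, ng = 12) {
    lanes <- simulate_lane_profiles(scenario_preset(preset),
                                    timepoints = c(-1, 5, 30),
                                    n_replicates = 1, n_genomes = ng,
                                    seed = 17)
    glance(coenrichment_from_lanes(lanes))
  }
  rab <- run("rnhAB")
  wt <- run("WT")
  expect_true(rab$peak_fraction %in% 5:7)
  expect_gt(rab$peak_value / rab$non_peak_mean,
            3 * wt$peak_value / wt$non_peak_mean)
})
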