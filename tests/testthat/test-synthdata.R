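# The scenario-driven generator: chromosome states, digestion, lanes,
# band tables, DRIP partitions, spot assays, synthesis series.

test_that("PD induction follows the dose and repair follows the class decay", {
  sc <- scenario_preset("rnhAB")
  expect_error(simulate_chromosome_state(sc, -5), "timepoint")
  sc_neg <- sc; sc_neg$dose <- -1
  expect_error(simulate_chromosome_state(sc_neg, 0), "dose")

  # no dose, no lesions, only baseline hybrids
  sc0 <- scenario_preset("rnhAB"); sc0$dose <- 0
  st0 <- simulate_chromosome_state(sc0, 30, seed = 1)
  expect_equal(nrow(st0$pd), 0)
  expect_true(all(is.na(st0$rdh$anchor)))

  # mean initial burden ~ dose x rate (~1500 at 36 J/m^2)
  counts <- vapply(1:40, function(i) {
    nrow(simulate_chromosome_state(sc, 0, seed = i)$pd)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 36 * 41.7),
            3 * stats::sd(counts) / sqrt(length(counts)))

  # pure fast class decays 2^-10 after ten half-lives (closed form)
  scf <- scenario_preset("WT")
  scf$slow_pd_fraction <- 0
  t10 <- scf$repair_lag_min + 10 * scf$fast_half_life
  left <- vapply(1:40, function(i) {
    nrow(simulate_chromosome_state(scf, t10, seed = 100 + i)$pd)
  }, numeric(1))
  expected <- 36 * 41.7 * 2^-10
  expect_lt(abs(mean(left) - expected), 3 * sqrt(expected / length(left)))
})

test_that("undamaged-repair scenarios keep the Poisson mean/variance ratio near 1", {
  sc <- scenario_preset("uvrA")  # no repair: counts stay Poisson
  counts <- vapply(1:100, function(i) {
    nrow(simulate_chromosome_state(sc, 5, seed = i)$pd)
  }, numeric(1))
  ratio <- stats::var(counts) / mean(counts)
  expect_gt(ratio, 0.65)
  expect_lt(ratio, 1.45)
})

test_that("digest conserves mass and lesions and honours the enzyme models", {
  sc <- scenario_preset("rnhAB")
  st <- simulate_chromosome_state(sc, 30, seed = 3)
  expect_error(digest(st, "NotAnEnzyme"), "Unknown enzyme")

  un <- digest(st, "uncut", seed = 4)
  expect_equal(nrow(un), 1)
  expect_equal(un$length, sc$genome_length)
  expect_equal(un$pd_count, nrow(st$pd))

  for (enz in c("HaeII", "EcoRI+BamHI", "sheared")) {
    fr <- digest(st, enz, seed = 5, protection_nt = sc$rdh_protection_nt)
    expect_equal(sum(fr$length), sc$genome_length)
    expect_equal(sum(fr$pd_count), nrow(st$pd))
    clipped <- sum(pmin(st$rdh$end, sc$genome_length) - pmax(st$rdh$start, 0))
    expect_equal(sum(fr$rdh_nt), clipped, tolerance = 1e-9)
    expect_true(all(fr$rdh_nt <= fr$length + 1e-9))
  }
})

test_that("hybrid-protected fragments run long under restriction digestion", {
  sc <- scenario_preset("rnhAB")
  st <- simulate_chromosome_state(sc, 30, seed = 11)
  fr <- digest(st, "HaeII", seed = 12, protection_nt = sc$rdh_protection_nt)
  bearers <- fr$length[fr$rdh_nt > 1000]
  expect_gt(length(bearers), 10)
  expect_gt(mean(bearers), 6000)   # hybrid + margin + flanks
})

test_that("render_lane integrates to the channel signal and orders sizes", {
  one <- tibble::tibble(length = 5000, pd_count = 2, rdh_nt = 0)
  attr(one, "enzyme") <- "uncut"
  prof <- render_lane(one, "southern", gain = 2, noise_cv = 0, seed = 1)
  integral <- sum(diff(prof$position) *
                  (head(prof$signal, -1) + tail(prof$signal, -1)) / 2)
  expect_equal(integral, 2 * 5000, tolerance = 1e-6)
  expect_true(all(diff(prof$position) > 0))

  # two populations: the larger migrates nearer the well
  two <- tibble::tibble(length = c(rep(9000, 50), rep(1200, 50)),
                        pd_count = 0, rdh_nt = 0)
  p2 <- render_lane(two, "southern", noise_cv = 0, seed = 2)
  m <- migration_model()
  x9 <- m$position(9); x12 <- m$position(1.2)
  expect_lt(x9, x12)
  near9 <- p2$signal[which.min(abs(p2$position - x9))]
  trough <- p2$signal[which.min(abs(p2$position - (x9 + x12) / 2))]
  expect_gt(near9, 3 * trough)

  expect_error(render_lane(two[0, ], "southern"), "empty")
  expect_error(render_lane(two, "weird"), "channel")
})

test_that("the HaeII digest's mass-weighted length distribution modes near 1.2 kb", {
  sc <- noise_free(scenario_preset("WT"))
  pool <- simulate_digest_pool(sc, -1, "HaeII", n_genomes = 4, seed = 9)
  # gel signal is mass-weighted: histogram fragment mass over length bins
  bins <- seq(100, 10000, by = 300)
  mass <- tapply(pool$length, cut(pool$length, bins), sum)
  mode_kb <- (bins[which.max(mass)] + 150) / 1000
  expect_gt(mode_kb, 0.7)
  expect_lt(mode_kb, 1.8)
})

test_that("band tables follow the Poisson zero class", {
  sc <- noise_free(scenario_preset("rnhAB"))
  sc$background_nicks_per_genome <- 0
  sc$dose <- 0
  bt <- simulate_band_table(sc, 5, "T4PDG", n_molecules = 500, seed = 1)
  expect_equal(supercoiled_fraction(bt$sc_signal, bt$rc_signal), 1)

  # mean one nick per plasmid: supercoiled fraction ~ e^-1
  sc1 <- noise_free(scenario_preset("uvrA"))  # no repair, clean decay-free
  sc1$background_nicks_per_genome <- 0
  sc1$pd_density_per_nt <- 1 / 9200
  f <- vapply(1:30, function(i) {
    b <- simulate_band_table(sc1, 5, "T4PDG", plasmid_length = 9200,
                             n_molecules = 2000, seed = i)
    supercoiled_fraction(b$sc_signal, b$rc_signal)
  }, numeric(1))
  expect_equal(mean(f), exp(-1), tolerance = 0.02)
  expect_error(simulate_band_table(sc1, 5, "T4PDG", n_molecules = 0), "n_molecules")
  expect_error(simulate_band_table(sc1, 5, "bleach"), "treatment")
})

test_that("DRIP partitions are mass-balanced and capture what they should", {
  sc <- clean_capture(scenario_preset("rnhAB_uvrA"))
  pool <- simulate_digest_pool(sc, 60, "HaeII", n_genomes = 3, seed = 31)
  d <- simulate_drip(pool, sc, seed = 32)
  # exact conservation per channel
  expect_equal(nrow(mass_balance_report(d)), 0)
  # perfect specific capture, no background: eluate holds no hybrid signal
  el_rdh <- d$signal[d$fraction == "eluate" & d$channel == "rdh"]
  expect_equal(el_rdh, 0)
  drip_rdh <- d$signal[d$fraction == "drip" & d$channel == "rdh"]
  expect_equal(drip_rdh, sum(pool$rdh_nt))
})

test_that("RNase HI treatment collapses hybrid capture toward background", {
  sc <- scenario_preset("rnhAB_uvrA")
  pool <- simulate_digest_pool(sc, 60, "HaeII", n_genomes = 5, seed = 41)
  un <- drip_enrichment(simulate_drip(pool, sc, seed = 42), "rdh")
  tr <- drip_enrichment(simulate_drip(pool, sc, rnase_treated = TRUE,
                                      seed = 43), "rdh")
  expect_lt(tr$drip_vs_eluate, un$drip_vs_eluate / 3)
})

test_that("spot assays scale tenfold per dilution and respect survival", {
  sc <- scenario_preset("uvrA_rnhAB_survival")
  sp <- simulate_spot_assay(sc, 0, titer = 2e8, seed = 51)
  by_dil <- tapply(sp$count, sp$dilution, mean)
  # adjacent dilutions differ ~10x in expectation
  ratios <- by_dil[1:4] / pmax(by_dil[2:5], 0.5)
  expect_true(all(ratios > 7 & ratios < 14))
  expect_error(simulate_spot_assay(sc, 12), "No survival configured")

  # survival 1: dose and no-dose titers agree within Poisson error
  sc1 <- scenario_preset("WT")
  t0 <- titer(simulate_spot_assay(sc1, 0, seed = 52))
  t6 <- titer(simulate_spot_assay(sc1, 0.6, seed = 53))
  expect_equal(mean(t6$titer) / mean(t0$titer), 1, tolerance = 0.1)
})

test_that("synthesis series are exactly dilution-correctable at zero noise", {
  sc <- scenario_preset("WT")
  raw <- simulate_synthesis_rates(sc, uv = TRUE, noise_cv = 0, seed = 61)
  ns <- normalize_synthesis(raw, "uv")
  truth <- stats::approx(sc$synthesis_rate$time_min, sc$synthesis_rate$rate,
                         xout = raw$time_min, rule = 2)$y
  expect_equal(ns$corrected, truth)
  # dilution log: raw counts drop 2x at each configured dilution
  expect_equal(unique(raw$cum_dilution[raw$time_min >= 150]), 8)
})

test_that("fixing the seed reproduces outputs byte-identically", {
  sc <- scenario_preset("rnhAB")
  a <- simulate_chromosome_state(sc, 30, seed = 99)
  b <- simulate_chromosome_state(sc, 30, seed = 99)
  expect_identical(a, b)
  expect_false(identical(
    a, simulate_chromosome_state(sc, 30, seed = 100)
  ))
  fa <- digest(a, "HaeII", seed = 7)
  fb <- digest(b, "HaeII", seed = 7)
  expect_identical(fa, fb)
  la <- render_lane(fa, "southern", seed = 8)
  expect_identical(la, render_lane(fb, "southern", seed = 8))
  da <- simulate_drip(fa, sc, seed = 9)
  expect_identical(da, simulate_drip(fb, sc, seed = 9))
  sa <- simulate_spot_assay(scenario_preset("WT"), 0, seed = 10)
  expect_identical(sa, simulate_spot_assay(scenario_preset("WT"), 0, seed = 10))
})

test_that("scenario YAML round-trips and rejects bad parameters", {
  sc <- scenario_preset("rnhAB_uvrA")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_equal(back$rdh_fold, sc$rdh_fold)
  expect_equal(back$p_spec, sc$p_spec)
  expect_equal(scenario_pd_count(back), scenario_pd_count(sc))
  expect_error(scenario("x", 36, p_spec = 1.5), "p_spec")
  expect_error(scenario("x", 36, nonsense = 1), "Unknown scenario parameter")
  expect_error(scenario("x", -2), "dose")
})
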