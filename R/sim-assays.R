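# Simulators for the band, blot, DRIP, spot and synthesis-rate assays.

#' Simulate a plasmid-relaxation band table
#'
#' Each plasmid molecule carries a Poisson number of cleavable lesions at
#' the scenario's current density under the given treatment (plus the
#' background nicking density); supercoiled signal is proportional to the
#' zero-nick class and relaxed signal to the rest, with multiplicative
#' log-normal band noise. `"none"` exposes only background nicking;
#' `"T4PDG"` exposes PDs; the RNase treatments expose DNA-ribonucleotides
#' (density 0 by default - the study's post-UV rN density did not rise).
#'
#' @param sc An `uvrdh_scenario`.
#' @param timepoint Minutes post-UV (`-1` = before UV).
#' @param treatment `"none"`, `"T4PDG"`, `"RNaseHII"` or `"RNaseHI"`.
#' @param plasmid_length Double-stranded plasmid length in nucleotides.
#' @param n_molecules Plasmid molecules per lane (>= 1).
#' @param rn_density_per_nt Ribonucleotide density exposed by the RNase
#'   treatments.
#' @param seed Optional seed.
#' @return One-row band tibble: `sample`, `time_min`, `treatment`,
#'   `sc_signal`, `rc_signal`.
#' @export
simulate_band_table <- function(sc, timepoint, treatment,
                                plasmid_length = 9200, n_molecules = 2000,
                                rn_density_per_nt = 0, seed = NULL) {
  assert_positive(plasmid_length, "plasmid_length")
  if (n_molecules < 1) abort("`n_molecules` must be at least 1.")
  if (!treatment %in% c("none", "T4PDG", "RNaseHII", "RNaseHI")) {
    abort(sprintf("Unknown treatment '%s'.", treatment))
  }
  d0 <- scenario_pd_count(sc) / sc$genome_length
  remaining <- if (timepoint == -1) 0 else {
    (1 - sc$slow_pd_fraction) *
      pd_survival_prob(timepoint, sc$plasmid_fast_half_life, sc$repair_lag_min) +
      sc$slow_pd_fraction *
        pd_survival_prob(timepoint, sc$plasmid_slow_half_life, sc$repair_lag_min)
  }
  treat_density <- switch(treatment,
    none = 0,
    T4PDG = d0 * remaining,
    RNaseHII = rn_density_per_nt,
    RNaseHI = rn_density_per_nt
  )
  bg_density <- sc$background_nicks_per_genome / sc$genome_length
  lambda <- plasmid_length * (treat_density + bg_density)
  with_local_seed(seed, {
    nicks <- rpois(n_molecules, lambda)
    sc_n <- sum(nicks == 0)
    noise <- rlnorm_cv(2, sc$noise_cv)
    tibble(
      sample = sc$strain, time_min = timepoint, treatment = treatment,
      sc_signal = sc_n * noise[1],
      rc_signal = (n_molecules - sc_n) * noise[2]
    )
  })
}

#' Simulate a full plasmid-relaxation time course (treated + untreated lanes)
#'
#' @param sc An `uvrdh_scenario`.
#' @param timepoints Minutes post-UV; include `-1` for the pre-UV point.
#' @param treatment Enzymatic treatment for the treated lanes.
#' @param n_replicates Independent gels.
#' @inheritParams simulate_band_table
#' @return Band tibble with both `"none"` and treated lanes per replicate
#'   and timepoint, plus a `replicate` column.
#' @export
simulate_relaxation_series <- function(sc, timepoints = c(-1, 5, 20, 60),
                                       treatment = "T4PDG",
                                       n_replicates = 3,
                                       plasmid_length = 9200,
                                       n_molecules = 2000, seed = NULL) {
  grid <- tidyr::expand_grid(
    replicate = seq_len(n_replicates), time_min = timepoints,
    trt = c("none", treatment)
  )
  purrr::pmap(grid, function(replicate, time_min, trt) {
    s <- derive_seed(seed, replicate * 811 + (time_min + 2) * 13 +
                       match(trt, c("none", treatment)))
    simulate_band_table(sc, time_min, trt, plasmid_length = plasmid_length,
                        n_molecules = n_molecules, seed = s) |>
      dplyr::mutate(replicate = replicate, .before = 1)
  }) |> dplyr::bind_rows()
}

#' Simulate western/southern blot measurements for whole-lane densitometry
#'
#' Southern signal reflects loaded DNA; the S9.6 western reflects total
#' hybrid nucleotides (baseline times the scenario's fold table) and the
#' anti-PD western reflects surviving PD density plus the non-specific
#' floor. All bands carry multiplicative log-normal noise.
#'
#' @param scenarios An `uvrdh_scenario` or list of them (one batch).
#' @param channel `"s96"` or `"pd"`.
#' @param timepoints Minutes post-UV (`-1` = log / pre-UV).
#' @param n_replicates Batches to simulate (each is one experiment with its
#'   own channel gains drawn once, as gels differ between experiments).
#' @param seed Optional seed.
#' @return Tibble: `batch`, `strain`, `channel`, `time_min`, `western`,
#'   `southern`.
#' @export
simulate_blot_measurements <- function(scenarios, channel = "s96",
                                       timepoints = c(-1, 5, 30, 60),
                                       n_replicates = 3, seed = NULL) {
  if (inherits(scenarios, "uvrdh_scenario")) scenarios <- list(scenarios)
  if (!channel %in% c("s96", "pd")) {
    abort("`channel` must be 's96' or 'pd'.")
  }
  purrr::map(seq_len(n_replicates), function(b) {
    bseed <- derive_seed(seed, b * 127)
    # per-experiment blot efficiencies (cancel within a batch, differ across)
    eff <- with_local_seed(bseed, rlnorm_cv(2, 0.3))
    purrr::imap(scenarios, function(sc, i) {
      d0 <- scenario_pd_count(sc) / sc$genome_length
      purrr::map(timepoints, function(t) {
        true_density <- if (channel == "s96") {
          sc$rdh_baseline_nt * rdh_fold_at(sc, t) / sc$genome_length
        } else {
          remaining <- if (t == -1) 0 else {
            (1 - sc$slow_pd_fraction) *
              pd_survival_prob(t, sc$fast_half_life, sc$repair_lag_min) +
              sc$slow_pd_fraction *
                pd_survival_prob(t, sc$slow_half_life, sc$repair_lag_min)
          }
          d0 * (remaining + sc$pd_blot_floor_frac)
        }
        s <- derive_seed(bseed, i * 101 + (t + 2))
        with_local_seed(s, {
          noise <- rlnorm_cv(2, sc$noise_cv)
          tibble(
            batch = b, strain = sc$strain, channel = channel, time_min = t,
            western = eff[1] * sc$channel_gains[[channel]] *
              true_density * noise[1],
            southern = eff[2] * sc$channel_gains$southern * noise[2]
          )
        })
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Simulate a DRIP (DNA:RNA immunoprecipitation) partition
#'
#' Every fragment is captured independently; the capture hazard combines
#' hybrid-specific capture (per full-length hybrid equivalent carried),
#' capture of the minor S9.6-sticky class, a per-PD capture boost (S9.6
#' recognises UV-damaged DNA), and non-specific background. RNase HI
#' treatment reduces each fragment's hybrid content to `rnase_survival` of
#' its value, which also removes its hybrid-specific capture; the
#' cross-reactive signal on sticky fragments survives. DRIP and eluate
#' totals sum exactly to the input per channel.
#'
#' @param fragments Fragment tibble from [digest()] or a pooled digest.
#' @param sc An `uvrdh_scenario` (capture parameters).
#' @param rnase_treated Was the sample RNase HI-treated before DRIP?
#' @param seed Optional seed.
#' @return Long tibble: `digest`, `rnase_treated`, `fraction`
#'   (`input`/`drip`/`eluate`), `channel` (`rdh`/`pd`/`dna`), `signal`.
#' @export
simulate_drip <- function(fragments, sc, rnase_treated = FALSE, seed = NULL) {
  assert_probability(sc$p_spec, "p_spec")
  assert_probability(sc$p_bg, "p_bg")
  enz <- attr(fragments, "enzyme") %||% "unknown"
  with_local_seed(seed, {
    n <- nrow(fragments)
    sticky <- runif(n) < sc$sticky_frac
    rdh_eff <- fragments$rdh_nt * if (rnase_treated) sc$rnase_survival else 1
    # cross-reactive S9.6 signal rides on sticky fragments, scaled to the
    # stated fraction of the (untreated) hybrid signal
    xreact_total <- sc$xreact_frac * sum(fragments$rdh_nt)
    xreact <- rep(0, n)
    if (any(sticky) && xreact_total > 0) {
      xreact[sticky] <- xreact_total * fragments$length[sticky] /
        sum(fragments$length[sticky])
    }
    p_cap <- 1 - (1 - sc$p_bg) *
      (1 - sc$p_stick * sticky) *
      (1 - sc$capture_pd_boost)^fragments$pd_count *
      (1 - sc$p_spec)^(rdh_eff / sc$rdh_length_mean)
    captured <- runif(n) < p_cap

    sig <- function(idx) c(
      rdh = sum(rdh_eff[idx]) + sum(xreact[idx]),
      pd = sum(fragments$pd_count[idx]),
      dna = sum(fragments$length[idx])
    )
    s_in <- sig(rep(TRUE, n)); s_drip <- sig(captured)
    tidyr::expand_grid(fraction = c("input", "drip", "eluate"),
                       channel = c("rdh", "pd", "dna")) |>
      dplyr::mutate(
        digest = enz, rnase_treated = rnase_treated, .before = 1
      ) |>
      dplyr::mutate(signal = unname(dplyr::case_when(
        .data$fraction == "input" ~ s_in[.data$channel],
        .data$fraction == "drip" ~ s_drip[.data$channel],
        TRUE ~ s_in[.data$channel] - s_drip[.data$channel]
      )))
  })
}

#' Simulate a serial-dilution spot assay
#'
#' Six cultures are spotted in five 10-fold serial dilutions (exponents
#' 0-5); counts are Poisson with mean titer x survival x spot volume x
#' 10^-dilution, with mild log-normal culture-to-culture titer variation.
#'
#' @param sc An `uvrdh_scenario` with a configured survival table.
#' @param dose UV dose (J/m^2); 0 means untreated. Any other dose must be
#'   present in the scenario's survival table.
#' @param titer True culture titer (CFU/ml).
#' @param volume_ml Spotted volume.
#' @param n_cultures Number of cultures.
#' @param seed Optional seed.
#' @return Tibble: `strain`, `dose`, `culture`, `dilution`, `count`,
#'   `volume_ml`.
#' @export
simulate_spot_assay <- function(sc, dose, titer = 2e8, volume_ml = 0.01,
                                n_cultures = 6, seed = NULL) {
  surv <- if (dose == 0) 1 else {
    hit <- sc$survival$survival[sc$survival$dose == dose]
    if (length(hit) != 1) {
      abort(sprintf("No survival configured for dose %g J/m^2 in scenario '%s'.",
                    dose, sc$strain))
    }
    hit
  }
  if (surv <= 0 || surv > 1) abort("true survival must lie in (0, 1].")
  with_local_seed(seed, {
    culture_titer <- titer * rlnorm_cv(n_cultures, 0.1)
    tidyr::expand_grid(culture = seq_len(n_cultures), dilution = 0:5) |>
      dplyr::mutate(
        strain = sc$strain, dose = dose, volume_ml = volume_ml,
        count = rpois(dplyr::n(),
                      culture_titer[.data$culture] * surv * volume_ml *
                        10^(-.data$dilution))
      ) |>
      dplyr::select("strain", "dose", "culture", "dilution", "count",
                    "volume_ml")
  })
}

#' Simulate a 3H-thymidine DNA synthesis rate time course
#'
#' Raw counts equal the scenario's true rate (interpolated from its
#' synthesis table) divided by the recorded cumulative dilution factor,
#' with multiplicative noise; cultures are diluted 2-fold at the
#' scenario's dilution times. The dilution log lets the analysis undo the
#' dilutions exactly.
#'
#' @param sc An `uvrdh_scenario`.
#' @param uv Simulate the UV-treated culture (TRUE) or the unirradiated
#'   control (constant true rate at the pre-UV level)?
#' @param times Sampling times (min; 0 = just before/at UV).
#' @param noise_cv Measurement noise CV (defaults to the scenario's).
#' @param seed Optional seed.
#' @return Tibble: `strain`, `uv`, `time_min`, `raw_counts`,
#'   `cum_dilution`.
#' @export
simulate_synthesis_rates <- function(sc, uv = TRUE,
                                     times = seq(0, 180, by = 10),
                                     noise_cv = NULL, seed = NULL) {
  cv <- noise_cv %||% sc$noise_cv
  # the time-0 sample is taken just before irradiation, so it carries the
  # pre-UV rate; inhibition appears from the first post-UV sample on
  pre_rate <- approx(sc$synthesis_rate$time_min, sc$synthesis_rate$rate,
                     xout = 0, rule = 2)$y
  truth <- if (uv) {
    approx(sc$synthesis_rate$time_min, sc$synthesis_rate$rate,
           xout = times, rule = 2)$y
  } else {
    rep(pre_rate, length(times))
  }
  cum_dil <- 2^vapply(times, function(t) sum(sc$dilution_times <= t),
                      numeric(1))
  with_local_seed(seed, {
    tibble(
      strain = sc$strain, uv = uv, time_min = times,
      raw_counts = truth / cum_dil * rlnorm_cv(length(times), cv),
      cum_dilution = cum_dil
    )
  })
}
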