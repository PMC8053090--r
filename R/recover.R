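# End-to-end recovery runs: generate data under a preset scenario and push
# it through the analysis pipeline, returning the study's headline numbers.
# These are the workhorses of the acceptance checks and the vignette.

#' Recover the genome-wide PD burden from synthetic relaxation gels
#'
#' Simulates T4-PDG plasmid-relaxation band tables at 36 J/m^2 and runs
#' supercoiled fraction -> mean nicks -> lesions per genome, averaging
#' replicate gels.
#'
#' @param n_replicates Replicate gels.
#' @param seed Seed.
#' @param plasmid_length_nt Plasmid length (double-stranded nt).
#' @return Estimated PDs per genome at 5 min post-UV.
#' @export
recover_pd_burden <- function(n_replicates = 200, seed = 7,
                              plasmid_length_nt = 9200) {
  sc <- scenario_preset("rnhAB")
  bt <- simulate_relaxation_series(sc, timepoints = c(-1, 5),
                                   n_replicates = n_replicates,
                                   plasmid_length = plasmid_length_nt,
                                   seed = seed)
  est <- suppressWarnings(
    estimate_lesion_density(bt, plasmid_length_nt = plasmid_length_nt)
  )
  est$lesions_per_genome[est$time_min == 5]
}

#' Recover chromosomal PD removal kinetics from synthetic blots
#'
#' Simulates anti-PD western / Southern series, applies the pd
#' normalization rule (5 min = 100%) and returns percent remaining per
#' timepoint, averaged over replicates.
#'
#' @param preset Strain preset name.
#' @param timepoints Minutes post-UV (include -1 and 5).
#' @param n_replicates Replicate experiments.
#' @param seed Seed.
#' @return Tibble: `time_min`, `percent_remaining`.
#' @export
recover_pd_removal <- function(preset, timepoints = c(-1, 5, 30, 60, 120),
                               n_replicates = 5, seed = 3) {
  b <- simulate_blot_measurements(scenario_preset(preset), channel = "pd",
                                  timepoints = timepoints,
                                  n_replicates = n_replicates, seed = seed)
  out <- suppressWarnings(normalize_series(b, rule = "pd"))
  out |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(percent_remaining = mean(.data$normalized),
                     .groups = "drop")
}

#' Recover the rnhAB hybrid fold increase (log to 60 min)
#'
#' @param n_replicates Replicate experiments.
#' @param seed Seed.
#' @return Fold change of normalized RDH density, log -> 60 min.
#' @export
recover_rdh_fold <- function(n_replicates = 5, seed = 5) {
  b <- simulate_blot_measurements(scenario_preset("rnhAB"), channel = "s96",
                                  timepoints = c(-1, 60),
                                  n_replicates = n_replicates, seed = seed)
  fold_change(normalize_series(b, rule = "rdh"), -1, 60)
}

#' Recover a strain's 16-fraction co-enrichment profile
#'
#' Simulates HaeII-digest lane profiles (southern, S9.6, anti-PD) at log,
#' 5 and 30 min post-UV and runs the full partition -> densities ->
#' normalize -> product pipeline.
#'
#' @param preset Strain preset name.
#' @param n_replicates Replicate experiments.
#' @param n_genomes Genomes pooled per lane.
#' @param seed Seed.
#' @return An `uvrdh_coenrichment`.
#' @export
recover_coenrichment <- function(preset, n_replicates = 3, n_genomes = 40,
                                 seed = 11) {
  lanes <- simulate_lane_profiles(scenario_preset(preset),
                                  timepoints = c(-1, 5, 30),
                                  n_replicates = n_replicates,
                                  n_genomes = n_genomes, seed = seed)
  coenrichment_from_lanes(lanes)
}

#' Recover the DRIP enrichment panel of the rnhAB uvrA scenario
#'
#' Simulates DRIP on sheared ("uncut" prep), EcoRI+BamHI- and
#' HaeII-digested chromosomal DNA at 60 min post 8 J/m^2, with and
#' without RNase HI treatment, and returns the replicate-averaged
#' enrichment panel.
#'
#' @param n_replicates Replicates per digest.
#' @param n_genomes Genomes pooled per DRIP input.
#' @param seed Seed.
#' @return One-row tibble: `uncut_rdh_vs_input`, `haeii_rdh_overall`,
#'   `haeii_rdh_overall_rnase`, `ebam_pd_vs_input`, `haeii_pd_vs_input`.
#' @export
recover_drip_panel <- function(n_replicates = 5, n_genomes = 10, seed = 13) {
  sc <- scenario_preset("rnhAB_uvrA")
  one <- function(r) {
    hae <- simulate_digest_pool(sc, 60, "HaeII", n_genomes = n_genomes,
                                seed = derive_seed(seed, 4 * r))
    d_hae <- simulate_drip(hae, sc, seed = derive_seed(seed, 4 * r + 1))
    d_trt <- simulate_drip(hae, sc, rnase_treated = TRUE,
                           seed = derive_seed(seed, 4 * r + 2))
    shr <- simulate_digest_pool(sc, 60, "sheared", n_genomes = n_genomes,
                                seed = derive_seed(seed, 4 * r + 3))
    d_shr <- simulate_drip(shr, sc, seed = derive_seed(seed, 4 * r + 17))
    eb <- simulate_digest_pool(sc, 60, "EcoRI+BamHI", n_genomes = n_genomes,
                               seed = derive_seed(seed, 4 * r + 31))
    d_eb <- simulate_drip(eb, sc, seed = derive_seed(seed, 4 * r + 47))
    tibble(
      uncut_rdh_vs_input = drip_enrichment(d_shr, "rdh")$drip_vs_input,
      haeii_rdh_overall = drip_enrichment(d_hae, "rdh")$drip_vs_eluate,
      haeii_rdh_overall_rnase = drip_enrichment(d_trt, "rdh")$drip_vs_eluate,
      ebam_pd_vs_input = drip_enrichment(d_eb, "pd")$drip_vs_input,
      haeii_pd_vs_input = drip_enrichment(d_hae, "pd")$drip_vs_input
    )
  }
  purrr::map(seq_len(n_replicates), one) |>
    dplyr::bind_rows() |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean))
}

#' Recover the triple-mutant kill factor at 0.6 J/m^2
#'
#' Simulates serial-dilution spot assays at 0 and 0.6 J/m^2 for the
#' uvrA rnhAB scenario and returns 1 / survival.
#'
#' @param seed Seed.
#' @return Fold reduction in survival.
#' @export
recover_survival_kill <- function(seed = 19) {
  sc <- scenario_preset("uvrA_rnhAB_survival")
  s0 <- simulate_spot_assay(sc, 0, seed = derive_seed(seed, 1))
  s6 <- simulate_spot_assay(sc, 0.6, seed = derive_seed(seed, 2))
  1 / survival_curve_point(s6, s0)$survival
}
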