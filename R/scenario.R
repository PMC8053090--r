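#' Scenario parameter bundles for the synthetic assay generator
#'
#' A scenario bundles every constant the generator needs to emulate one
#' strain under one UV dose: lesion induction and repair kinetics, RNA:DNA
#' hybrid (RDH) abundance and geometry, gel/blot channel gains and noise,
#' immunoprecipitation capture behaviour, survival and DNA-synthesis truth
#' tables. Scenarios are plain lists (class `uvrdh_scenario`) so they can be
#' written to and read from YAML with [write_scenario()] / [read_scenario()].
#'
#' Time is in minutes post-UV throughout; `-1` encodes the pre-UV ("log")
#' sample. Lengths and positions are nucleotides (nt) on a single linear
#' genome; the default genome length of 9.2e6 nt is the *E. coli* genome
#' counted in nucleotides. Doses are J/m^2.
#'
#' Key parameter groups:
#' \describe{
#'   \item{PD induction}{`pd_induction_rate` (PDs per J/m^2 per genome,
#'     default 41.7) or the override `pd_density_per_nt` used by DRIP
#'     scenarios, where PD burden is specified as a density (1 per 10 kb).}
#'   \item{Repair kinetics}{Two-class exponential decay. A PD is "slow"
#'     with probability `slow_pd_fraction`; classes decay with
#'     `fast_half_life` / `slow_half_life` (chromosomal assays) or the
#'     `plasmid_*` pair (plasmid relaxation assays) after an engagement lag
#'     of `repair_lag_min`. `Inf` half-lives encode excision-deficient
#'     (uvrA) strains.}
#'   \item{RDH structure}{Baseline hybrids total `rdh_baseline_nt` nt in
#'     short (`rdh_baseline_length` nt) dispersed stretches. UV-induced
#'     hybrids follow the per-timepoint `rdh_fold` table (total hybrid nt
#'     relative to baseline). If `rdh_induced_dispersed` is FALSE the
#'     induced hybrids are full-length structures (`rdh_length_mean`,
#'     gamma-shaped with `rdh_length_shape`) anchored each at one surviving
#'     slow PD, and restriction cutting is suppressed across the hybrid
#'     plus `rdh_protection_nt` on each side.}
#'   \item{Blot channels}{`channel_gains`, multiplicative log-normal
#'     `noise_cv`, and the anti-PD western's non-specific background as a
#'     fraction of the initial PD signal: `pd_floor_frac` for gel-lane
#'     fraction profiles (membrane background matters in signal-poor
#'     fractions) and the smaller `pd_blot_floor_frac` for integrated
#'     whole-lane band quantification.}
#'   \item{DRIP capture}{`p_spec` (hybrid-bearing fragments), `p_bg`
#'     (non-specific), a minor S9.6-sticky fragment class (`sticky_frac`,
#'     `p_stick`) carrying cross-reactive signal `xreact_frac` of the
#'     hybrid signal, a per-PD capture boost `capture_pd_boost`, and
#'     `rnase_survival` (fraction of hybrid structures surviving RNase HI).}
#' }
#'
#' @param strain Strain label.
#' @param dose UV dose in J/m^2.
#' @param ... Named parameter overrides; see Details for the full set.
#' @return An `uvrdh_scenario` object (a validated named list).
#' @examples
#' sc <- scenario("rnhAB", dose = 36)
#' sc$slow_pd_fraction
#' @export
scenario <- function(strain = "WT", dose = 36, ...) {
  defaults <- list(
    strain = strain,
    dose = dose,
    genome_length = 9.2e6,
    pd_induction_rate = 41.7,
    pd_density_per_nt = NULL,
    slow_pd_fraction = 0.02,
    repair_lag_min = 5,
    fast_half_life = 6,
    slow_half_life = 60,
    plasmid_fast_half_life = 15,
    plasmid_slow_half_life = 60,
    rdh_length_mean = 3500,
    rdh_length_shape = 12,
    rdh_baseline_nt = 6125,
    rdh_baseline_length = 300,
    rdh_fold = tibble(time_min = c(-1, 0, 10, 30, 60, 120),
                      fold = c(1, 1, 1, 3.2, 4, 1.5)),
    rdh_induced_dispersed = TRUE,
    rdh_protection_nt = 1500,
    channel_gains = list(southern = 1, s96 = 1, pd = 1),
    noise_cv = 0.15,
    pd_floor_frac = 0.10,
    pd_blot_floor_frac = 0.03,
    background_nicks_per_genome = 45,
    p_spec = 0.69,
    p_bg = 0.003,
    sticky_frac = 0.01,
    p_stick = 0.29,
    capture_pd_boost = 0.04,
    xreact_frac = 0.01,
    rnase_survival = 0.01,
    shear_mean_nt = 5500,
    digest_tail_frac = 0.006,
    digest_tail_mean_nt = 30000,
    survival = tibble(dose = numeric(), survival = numeric()),
    synthesis_rate = tibble(time_min = c(0, 10, 30, 40, 60, 180),
                            rate = c(1, 0.05, 0.05, 0.6, 1.2, 1.2)),
    dilution_times = c(50, 90, 150),
    seed = NULL
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown scenario parameter(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  sc <- defaults
  sc[names(overrides)] <- overrides
  validate_scenario(structure(sc, class = "uvrdh_scenario"))
}

validate_scenario <- function(sc) {
  assert_non_negative(sc$dose, "dose")
  assert_positive(sc$genome_length, "genome_length")
  assert_positive(sc$pd_induction_rate, "pd_induction_rate")
  if (!is.null(sc$pd_density_per_nt)) {
    assert_positive(sc$pd_density_per_nt, "pd_density_per_nt")
  }
  assert_probability(sc$slow_pd_fraction, "slow_pd_fraction")
  for (f in c("fast_half_life", "slow_half_life",
              "plasmid_fast_half_life", "plasmid_slow_half_life")) {
    if (!(is.numeric(sc[[f]]) && length(sc[[f]]) == 1 && sc[[f]] > 0)) {
      abort(sprintf("`%s` must be a positive number (Inf allowed).", f))
    }
  }
  assert_positive(sc$rdh_length_mean, "rdh_length_mean")
  assert_positive(sc$rdh_length_shape, "rdh_length_shape")
  assert_non_negative(sc$rdh_baseline_nt, "rdh_baseline_nt")
  assert_positive(sc$rdh_baseline_length, "rdh_baseline_length")
  assert_non_negative(sc$rdh_protection_nt, "rdh_protection_nt")
  assert_probability(sc$digest_tail_frac, "digest_tail_frac")
  assert_positive(sc$digest_tail_mean_nt, "digest_tail_mean_nt")
  if (any(sc$rdh_fold$fold < 0)) abort("`rdh_fold$fold` must be >= 0.")
  assert_non_negative(sc$noise_cv, "noise_cv")
  assert_non_negative(sc$pd_floor_frac, "pd_floor_frac")
  assert_non_negative(sc$pd_blot_floor_frac, "pd_blot_floor_frac")
  assert_non_negative(sc$background_nicks_per_genome,
                      "background_nicks_per_genome")
  for (p in c("p_spec", "p_bg", "sticky_frac", "p_stick",
              "capture_pd_boost", "rnase_survival")) {
    assert_probability(sc[[p]], p)
  }
  for (g in names(sc$channel_gains)) {
    assert_positive(sc$channel_gains[[g]], paste0("channel_gains$", g))
  }
  if (nrow(sc$survival) > 0) {
    if (any(sc$survival$survival <= 0) || any(sc$survival$survival > 1)) {
      abort("`survival$survival` values must lie in (0, 1].")
    }
  }
  sc
}

#' @export
print.uvrdh_scenario <- function(x, ...) {
  cat(sprintf("<uvrdh_scenario> strain %s, %.3g J/m^2\n", x$strain, x$dose))
  dens <- if (is.null(x$pd_density_per_nt)) {
    sprintf("%.1f PDs/J/m^2/genome", x$pd_induction_rate)
  } else {
    sprintf("1 PD per %.3g nt", 1 / x$pd_density_per_nt)
  }
  cat(sprintf("  PD induction: %s; slow fraction %.2f\n",
              dens, x$slow_pd_fraction))
  cat(sprintf("  repair t1/2 (chromosome): fast %g min, slow %g min\n",
              x$fast_half_life, x$slow_half_life))
  cat(sprintf("  RDH baseline %g nt, induced %s\n", x$rdh_baseline_nt,
              if (x$rdh_induced_dispersed) "dispersed" else "anchored"))
  invisible(x)
}

#' Preconfigured scenarios for the strains of the UV/RDH study
#'
#' Returns a scenario whose constants are calibrated so that the analysis
#' pipeline, run on data generated from it, reproduces the study's printed
#' checkpoints (PD burden and removal kinetics, RDH fold increases, the
#' 16-fraction co-enrichment profile, DRIP enrichments, UV survival).
#'
#' Available presets: `"WT"`, `"rnhA"`, `"rnhB"`, `"rnhAB"`, `"rnhAB_rpoB"`,
#' `"uvrA"`, `"rnhAB_uvrA"` (the DRIP strain, 8 J/m^2, PD density 1/10 kb),
#' `"uvrA_rnhAB_survival"` (the triple-mutant survival scenario), `"recF"`,
#' `"recF_rnhAB"` (built multiplicatively from the two single defects).
#'
#' @param name Preset name.
#' @param dose Optional UV dose override (J/m^2).
#' @return An `uvrdh_scenario`.
#' @examples
#' scenario_preset("rnhAB")
#' @export
scenario_preset <- function(name, dose = NULL) {
  fold_tbl <- function(t, f) tibble(time_min = t, fold = f)
  base_times <- c(-1, 0, 10, 30, 60, 120)
  sc <- switch(name,
    WT = scenario("WT", 36,
      slow_pd_fraction = 0.02,
      rdh_baseline_nt = 6125,
      rdh_fold = fold_tbl(base_times, c(1, 1, 1, 3.2, 4, 1.5)),
      rdh_induced_dispersed = TRUE,
      survival = tibble(dose = c(0.6, 5, 10, 20),
                        survival = c(1, 0.9, 0.5, 0.1)),
      synthesis_rate = tibble(time_min = c(0, 10, 30, 40, 60, 180),
                              rate = c(1, 0.05, 0.05, 0.6, 1.2, 1.2))
    ),
    rnhA = scenario("rnhA", 36,
      slow_pd_fraction = 0.10,
      rdh_baseline_nt = 26250,
      rdh_fold = fold_tbl(base_times, c(1, 1, 1, 4, 9, 3)),
      rdh_induced_dispersed = TRUE
    ),
    rnhB = scenario("rnhB", 36,
      slow_pd_fraction = 0.02,
      rdh_baseline_nt = 6125,
      rdh_fold = fold_tbl(base_times, c(1, 1, 1, 3.2, 4, 1.5)),
      rdh_induced_dispersed = TRUE
    ),
    rnhAB = scenario("rnhAB", 36,
      slow_pd_fraction = 0.19,
      slow_half_life = 57,
      rdh_fold = fold_tbl(base_times, c(1, 1, 1, 5.2, 13, 12)),
      rdh_induced_dispersed = FALSE,
      rdh_protection_nt = 1300,
      rdh_baseline_nt = 45000,
      survival = tibble(dose = c(0.6, 5, 10, 20),
                        survival = c(1, 0.4, 0.08, 0.004)),
      synthesis_rate = tibble(time_min = c(0, 10, 50, 90, 120, 180),
                              rate = c(0.5, 0.02, 0.02, 0.25, 0.3, 0.3))
    ),
    rnhAB_rpoB = scenario("rnhAB_rpoB", 36,
      slow_pd_fraction = 0.02,
      rdh_baseline_nt = 87500,
      rdh_fold = fold_tbl(base_times, c(1, 1, 1, 2.5, 5, 2)),
      rdh_induced_dispersed = TRUE
    ),
    uvrA = scenario("uvrA", 36,
      slow_pd_fraction = 0,
      fast_half_life = Inf, slow_half_life = Inf,
      plasmid_fast_half_life = Inf, plasmid_slow_half_life = Inf,
      rdh_baseline_nt = 17500,
      rdh_fold = fold_tbl(base_times, c(1, 1, 1, 2, 2, 2)),
      rdh_induced_dispersed = TRUE,
      synthesis_rate = tibble(time_min = c(0, 10, 180),
                              rate = c(1, 0.03, 0.03))
    ),
    rnhAB_uvrA = scenario("rnhAB_uvrA", 8,
      pd_density_per_nt = 1e-4,
      slow_pd_fraction = 0.20,
      fast_half_life = Inf, slow_half_life = Inf,
      plasmid_fast_half_life = Inf, plasmid_slow_half_life = Inf,
      rdh_baseline_nt = 4040,
      rdh_fold = fold_tbl(c(-1, 0, 10, 30, 60, 120),
                          c(1, 1, 1, 5, 14, 14)),
      rdh_induced_dispersed = FALSE,
      rdh_protection_nt = 0,
      digest_tail_frac = 0
    ),
    uvrA_rnhAB_survival = scenario("uvrA rnhAB", 0.6,
      survival = tibble(dose = 0.6, survival = 0.05)
    ),
    recF = scenario("recF", 10,
      survival = tibble(dose = c(2, 5, 10), survival = c(0.8, 0.3, 0.05))
    ),
    recF_rnhAB = scenario("recF rnhAB", 10,
      survival = tibble(dose = c(2, 5, 10),
                        survival = c(0.8, 0.3, 0.05) * c(0.9, 0.4, 0.08))
    ),
    abort(sprintf("Unknown scenario preset '%s'.", name))
  )
  if (!is.null(dose)) sc$dose <- dose
  validate_scenario(sc)
}

#' Read and write scenarios as YAML
#'
#' Scenario files hold one document per strain-by-dose condition. Tables
#' (`rdh_fold`, `survival`, `synthesis_rate`) round-trip as column lists.
#'
#' @param path File path.
#' @param sc An `uvrdh_scenario`.
#' @return `read_scenario()` returns an `uvrdh_scenario`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  for (tab in c("rdh_fold", "survival", "synthesis_rate")) {
    if (!is.null(raw[[tab]])) raw[[tab]] <- as_tibble(raw[[tab]])
  }
  do.call(scenario, c(list(strain = raw$strain, dose = raw$dose),
                      raw[setdiff(names(raw), c("strain", "dose"))]))
}

#' @rdname read_scenario
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "uvrdh_scenario"))
  out <- unclass(sc)
  for (tab in c("rdh_fold", "survival", "synthesis_rate")) {
    out[[tab]] <- as.list(out[[tab]])
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

# Interpolate the RDH fold table at arbitrary timepoints (linear, constant
# beyond the table's range). Pre-UV (-1) always evaluates from the table.
rdh_fold_at <- function(sc, time_min) {
  tb <- sc$rdh_fold
  if (nrow(tb) == 1) return(rep(tb$fold, length(time_min)))
  approx(tb$time_min, tb$fold, xout = time_min, rule = 2)$y
}

# Surviving-PD probability for one repair class at `time_min` post-UV.
# Removal is exponential with the class half-life after an engagement lag.
pd_survival_prob <- function(time_min, half_life, lag) {
  t_eff <- pmax(0, time_min - lag)
  ifelse(time_min < 0, 0, 2^(-t_eff / half_life))
}

# Genome-wide initial PD count implied by a scenario (dose x rate, or the
# density override used by the DRIP scenarios).
scenario_pd_count <- function(sc) {
  if (!is.null(sc$pd_density_per_nt)) {
    sc$pd_density_per_nt * sc$genome_length
  } else {
    sc$dose * sc$pd_induction_rate
  }
}
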