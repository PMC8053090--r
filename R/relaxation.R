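# Poisson zero-class lesion density estimation from plasmid topoisomer bands.

#' Fraction of supercoiled plasmid in a lane
#'
#' The supercoiled monomer signal divided by the sum of supercoiled and
#' relaxed monomer signals. Multimer bands are outside the quantification.
#'
#' @param supercoiled,relaxed Band intensities (>= 0, sum > 0). Vectorised.
#' @return Fraction in [0, 1].
#' @examples
#' supercoiled_fraction(800, 200)  # 0.8
#' @export
supercoiled_fraction <- function(supercoiled, relaxed) {
  assert_non_negative(supercoiled, "supercoiled")
  assert_non_negative(relaxed, "relaxed")
  total <- supercoiled + relaxed
  if (any(total <= 0)) {
    abort("Cannot quantify a lane with zero total band signal.")
  }
  supercoiled / total
}

#' Mean nicks per plasmid from the Poisson zero class
#'
#' Supercoiled molecules are the zero class of a Poisson distribution of
#' nicks, so the mean number of enzyme-revealed nicks per plasmid is
#' `-ln(F_treated / F_untreated)`; the untreated lane's supercoiled
#' fraction absorbs background nicking. A treated fraction above the
#' untreated one (blot noise) is clamped to zero nicks with a warning;
#' a treated fraction of zero means saturation (every plasmid nicked).
#'
#' @param f_treated,f_untreated Supercoiled fractions in (0, 1]. Vectorised.
#' @return Mean nicks per plasmid (>= 0; `Inf` when saturated).
#' @examples
#' mean_nicks(exp(-1) * 0.9, 0.9)  # 1.0
#' @export
mean_nicks <- function(f_treated, f_untreated) {
  assert_non_negative(f_treated, "f_treated")
  if (any(f_untreated <= 0) || any(f_untreated > 1)) {
    abort("`f_untreated` must lie in (0, 1].")
  }
  if (any(f_treated == 0)) {
    warn("F_treated = 0: every plasmid is nicked; density is saturated (Inf).")
  }
  over <- f_treated > f_untreated
  if (any(over)) {
    warn(sprintf(
      "%d lane(s) have F_treated > F_untreated; nick estimate clamped to 0 (blot noise, not signal).",
      sum(over)
    ))
  }
  pmax(0, -log(f_treated / f_untreated))
}

#' Convert nicks per plasmid to lesions per genome
#'
#' The nick density (plasmid nucleotides per nick) is scaled to the genome:
#' `genome_length * mean_nicks / plasmid_length`. Plasmid length is counted
#' in double-stranded nucleotides (2 x bp), the unit the density formula
#' uses.
#'
#' @param mean_nicks Mean nicks per plasmid (>= 0). Vectorised.
#' @param plasmid_length_nt Double-stranded plasmid length (nt, > 0).
#' @param genome_length_nt Genome length (nt; default 9.2e6).
#' @return Lesions per genome.
#' @examples
#' lesions_per_genome(1.5, 9200)  # 1500
#' @export
lesions_per_genome <- function(mean_nicks, plasmid_length_nt,
                               genome_length_nt = 9.2e6) {
  assert_non_negative(mean_nicks, "mean_nicks")
  assert_positive(plasmid_length_nt, "plasmid_length_nt")
  assert_positive(genome_length_nt, "genome_length_nt")
  genome_length_nt * mean_nicks / plasmid_length_nt
}

#' Estimate lesion densities from a plasmid-relaxation band table
#'
#' Pairs each treated lane with the untreated (`"none"`) lane of the same
#' replicate and timepoint, applies the zero-class formula and converts to
#' lesions per genome. Replicate gels are pooled by averaging the per-gel
#' estimates (set `pool = "fractions"` to average supercoiled fractions
#' before estimating instead).
#'
#' @param band_table Tibble with columns `time_min`, `treatment`,
#'   `sc_signal`, `rc_signal` and optionally `replicate`.
#' @param plasmid_length_nt Double-stranded plasmid length (nt).
#' @param genome_length_nt Genome length (nt).
#' @param pool `"estimates"` (default) or `"fractions"`.
#' @return Tibble: `time_min`, `treatment`, `mean_nicks`,
#'   `lesions_per_genome`, `n_gels` (plus per-replicate rows when
#'   `pool = "none"`).
#' @examples
#' bt <- simulate_relaxation_series(scenario_preset("rnhAB"),
#'   timepoints = c(-1, 5), n_replicates = 2, seed = 1)
#' estimate_lesion_density(bt, plasmid_length_nt = 9200)
#' @export
estimate_lesion_density <- function(band_table, plasmid_length_nt,
                                    genome_length_nt = 9.2e6,
                                    pool = c("estimates", "fractions", "none")) {
  pool <- match.arg(pool)
  bt <- band_table
  if (!"replicate" %in% names(bt)) bt$replicate <- 1L
  bt <- dplyr::mutate(bt,
    f = supercoiled_fraction(.data$sc_signal, .data$rc_signal)
  )
  untreated <- dplyr::filter(bt, .data$treatment == "none") |>
    dplyr::select("replicate", "time_min", f_untreated = "f")
  treated <- dplyr::filter(bt, .data$treatment != "none")
  if (nrow(treated) == 0 || nrow(untreated) == 0) {
    abort("Band table needs both treated and untreated ('none') lanes.")
  }
  paired <- dplyr::inner_join(treated, untreated,
                              by = c("replicate", "time_min"))
  if (pool == "fractions") {
    paired <- paired |>
      dplyr::group_by(.data$time_min, .data$treatment) |>
      dplyr::summarise(f = mean(.data$f),
                       f_untreated = mean(.data$f_untreated),
                       n_gels = dplyr::n(), .groups = "drop")
  }
  est <- paired |>
    dplyr::mutate(
      mean_nicks = mean_nicks(.data$f, .data$f_untreated),
      lesions_per_genome = lesions_per_genome(
        .data$mean_nicks, plasmid_length_nt, genome_length_nt
      )
    )
  if (pool == "estimates") {
    est <- est |>
      dplyr::group_by(.data$time_min, .data$treatment) |>
      dplyr::summarise(
        mean_nicks = mean(.data$mean_nicks),
        lesions_per_genome = mean(.data$lesions_per_genome),
        n_gels = dplyr::n(), .groups = "drop"
      )
  }
  dplyr::select(est, dplyr::any_of(c(
    "replicate", "time_min", "treatment", "mean_nicks",
    "lesions_per_genome", "n_gels"
  )))
}

#' Percent of lesions remaining relative to a reference timepoint
#'
#' Subtracts the pre-UV background estimate (the `-1` "before UV" point,
#' when present) from every point, then expresses each as a percentage of
#' the reference timepoint (5 min post-UV by convention). Negative
#' background-subtracted values are clipped at zero with a warning.
#'
#' @param estimates Tibble with `time_min` and `lesions_per_genome` (one
#'   row per timepoint, e.g. from [estimate_lesion_density()]).
#' @param reference_timepoint Timepoint taken as 100 (default 5 min).
#' @return Tibble: `time_min`, `lesions_per_genome`, `percent_remaining`.
#' @export
percent_remaining <- function(estimates, reference_timepoint = 5) {
  if (!reference_timepoint %in% estimates$time_min) {
    abort(sprintf("Reference timepoint %g min is missing from the series.",
                  reference_timepoint))
  }
  bg <- estimates$lesions_per_genome[estimates$time_min == -1]
  bg <- if (length(bg) == 0) 0 else mean(bg)
  adj <- estimates$lesions_per_genome - bg
  if (any(adj < 0)) {
    warn(sprintf("%d point(s) fell below the pre-UV background; clipped to 0.",
                 sum(adj < 0)))
    adj <- pmax(0, adj)
  }
  ref <- adj[estimates$time_min == reference_timepoint][1]
  if (ref <= 0) abort("Reference timepoint has no signal above background.")
  dplyr::mutate(
    dplyr::select(estimates, "time_min", "lesions_per_genome"),
    percent_remaining = 100 * adj / ref
  )
}
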