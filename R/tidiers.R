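# broom-style tidiers for the package's result objects.

#' Tidy a co-enrichment profile
#'
#' @param x An `uvrdh_coenrichment`.
#' @param ... Unused.
#' @return One row per fraction: `fraction`, `norm_rdh`, `norm_pd`,
#'   `coenrichment`, `size_hi_kb`, `size_lo_kb`.
#' @method tidy uvrdh_coenrichment
#' @export
tidy.uvrdh_coenrichment <- function(x, ...) {
  x$profile
}

#' One-row summary of a co-enrichment profile
#'
#' @param x An `uvrdh_coenrichment`.
#' @param ... Unused.
#' @return Tibble: `peak_fraction`, `peak_value`, `non_peak_mean`,
#'   `mean_value`, `peak_size_lo_kb`, `peak_size_hi_kb`.
#' @method glance uvrdh_coenrichment
#' @export
glance.uvrdh_coenrichment <- function(x, ...) {
  tibble(
    peak_fraction = x$peak_fraction,
    peak_value = x$peak_value,
    non_peak_mean = x$non_peak_mean,
    mean_value = x$mean_value,
    peak_size_lo_kb = x$profile$size_lo_kb[x$peak_fraction],
    peak_size_hi_kb = x$profile$size_hi_kb[x$peak_fraction]
  )
}

#' Tidy a scenario's key constants
#'
#' @param x An `uvrdh_scenario`.
#' @param ... Unused.
#' @return One-row tibble of the headline scenario constants.
#' @method tidy uvrdh_scenario
#' @export
tidy.uvrdh_scenario <- function(x, ...) {
  tibble(
    strain = x$strain, dose = x$dose,
    pd_per_genome = scenario_pd_count(x),
    slow_pd_fraction = x$slow_pd_fraction,
    fast_half_life = x$fast_half_life,
    slow_half_life = x$slow_half_life,
    rdh_baseline_nt = x$rdh_baseline_nt,
    rdh_length_mean = x$rdh_length_mean
  )
}
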