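# DRIP enrichment ratios and the anchored-PD co-occurrence expectation.

# Densities (western / DNA) per fraction from a long DRIP table.
drip_densities <- function(drip_tbl, channel) {
  wide <- drip_tbl |>
    dplyr::filter(.data$channel %in% c(channel, "dna")) |>
    tidyr::pivot_wider(names_from = "channel", values_from = "signal")
  if (any(wide$dna <= 0)) abort("DNA signal must be > 0 in every fraction.")
  setNames(wide[[channel]] / wide$dna, wide$fraction)
}

#' DRIP or eluate enrichment relative to the input fraction
#'
#' The ratio of a fraction's density (western signal / DNA signal) to the
#' input fraction's density; applies identically to the RDH and PD
#' channels.
#'
#' @param fraction_density Density of the DRIP (or eluate) fraction.
#' @param input_density Density of the input fraction (> 0).
#' @return Fold enrichment.
#' @examples
#' enrichment(2, 0.2)  # 10
#' @export
enrichment <- function(fraction_density, input_density) {
  if (any(input_density <= 0)) abort("`input_density` must be > 0.")
  fraction_density / input_density
}

#' Overall enrichment: DRIP density over eluate density
#'
#' @param drip_density,eluate_density Fraction densities.
#' @return Fold; a zero eluate density returns `Inf` with a warning
#'   (complete depletion).
#' @export
overall_enrichment <- function(drip_density, eluate_density) {
  if (any(eluate_density == 0)) {
    warn("Eluate density is 0; overall enrichment reported as Inf.")
  }
  drip_density / eluate_density
}

#' Enrichment table from a simulated or measured DRIP partition
#'
#' @param drip_tbl Long DRIP tibble (`fraction`, `channel`, `signal`, plus
#'   id columns).
#' @param channel `"rdh"` or `"pd"`.
#' @return One-row tibble: `drip_vs_input`, `eluate_vs_input`,
#'   `drip_vs_eluate`.
#' @export
drip_enrichment <- function(drip_tbl, channel = "rdh") {
  d <- drip_densities(drip_tbl, channel)
  tibble(
    channel = channel,
    drip_vs_input = enrichment(d[["drip"]], d[["input"]]),
    eluate_vs_input = enrichment(d[["eluate"]], d[["input"]]),
    drip_vs_eluate = overall_enrichment(d[["drip"]], d[["eluate"]])
  )
}

#' Theoretical maximal PD enrichment under the anchored-PD model
#'
#' Each hybrid is anchored at one PD; the DNA span a captured hybrid drags
#' along (the larger of the mean fragment and mean hybrid length, `S`)
#' additionally carries Poisson background PDs at density `lambda`. The
#' maximal PD enrichment of perfectly captured hybrid spans over bulk DNA
#' is then `(1 + lambda * S) / (lambda * S)`: strictly decreasing in both
#' `lambda` and `S`, approaching 1 as `lambda * S` grows (long fragments
#' or dense PDs bury the anchor signal).
#'
#' @param pd_density_per_nt Background PD density (PDs per nt, > 0).
#' @param mean_fragment_nt Mean fragment length (nt, > 0).
#' @param mean_rdh_nt Mean hybrid length (nt, > 0).
#' @return Expected maximal fold enrichment.
#' @examples
#' expected_max_pd_enrichment(1e-4, 1200, 3500)  # ~3.86
#' @export
expected_max_pd_enrichment <- function(pd_density_per_nt, mean_fragment_nt,
                                       mean_rdh_nt) {
  assert_positive(pd_density_per_nt, "pd_density_per_nt")
  assert_positive(mean_fragment_nt, "mean_fragment_nt")
  assert_positive(mean_rdh_nt, "mean_rdh_nt")
  s <- pmax(mean_fragment_nt, mean_rdh_nt)
  ls <- pd_density_per_nt * s
  (1 + ls) / ls
}

#' Mass-balance QC for simulated DRIP partitions
#'
#' Simulated partitions must satisfy drip + eluate = input exactly per
#' channel; measured tables (independent blots per fraction) need not, and
#' are reported as not applicable.
#'
#' @param drip_tbl Long DRIP tibble.
#' @param simulated Is this a simulated partition (default TRUE)?
#' @param tol Relative tolerance (default 1e-6).
#' @return Tibble of flags (`channel`, `input`, `drip_plus_eluate`,
#'   `rel_error`); empty when conserved. For measured data a one-row
#'   tibble with `applicable = FALSE`.
#' @export
mass_balance_report <- function(drip_tbl, simulated = TRUE, tol = 1e-6) {
  if (!simulated) {
    return(tibble(applicable = FALSE,
                  note = "independent blots; mass balance not expected"))
  }
  wide <- tidyr::pivot_wider(drip_tbl, names_from = "fraction",
                             values_from = "signal")
  wide |>
    dplyr::mutate(
      drip_plus_eluate = .data$drip + .data$eluate,
      rel_error = abs(.data$drip_plus_eluate - .data$input) /
        pmax(.data$input, .Machine$double.eps)
    ) |>
    dplyr::filter(.data$rel_error > tol) |>
    dplyr::select("channel", "input", "drip_plus_eluate", "rel_error")
}
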