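# Western/Southern blot densitometry with the study's two normalization
# rules: hybrid densities to the rnhAB log culture of the same experiment,
# PD densities to the same strain's 5-min post-UV point (= 100%).

#' Band density: western over southern signal
#'
#' @param western Western band intensity (>= 0). Vectorised.
#' @param southern Matching Southern (DNA loading) intensity (> 0).
#' @return Density (signal per DNA).
#' @examples
#' band_density(10, 5)  # 2
#' @export
band_density <- function(western, southern) {
  assert_non_negative(western, "western")
  if (any(southern <= 0)) {
    abort("`southern` must be > 0 to report a density.")
  }
  western / southern
}

#' Normalize a batch of blot densities by the study's rules
#'
#' Rule `"rdh"` divides every density in a batch by that batch's rnhAB
#' log-culture density (hybrid signals are only comparable across
#' experiments after this within-batch anchoring). Rule `"pd"` first
#' subtracts each strain's pre-UV background density (the `-1` / log
#' point, when present and `subtract_background = TRUE`), then expresses
#' each strain's series as percent of its own 5-min post-UV density.
#'
#' @param blots Tibble with columns `batch`, `strain`, `time_min`,
#'   `western`, `southern` (a `channel` column is carried through).
#' @param rule `"rdh"` or `"pd"`.
#' @param reference_strain Strain anchoring the rdh rule (default
#'   `"rnhAB"`).
#' @param reference_time Reference timepoint: `-1` (log) for rdh, `5` for
#'   pd.
#' @param subtract_background For the pd rule, subtract the strain's
#'   pre-UV density first (default TRUE; sub-background values floor at 0
#'   with a logged count).
#' @return The input plus `density` and `normalized` columns (`normalized`
#'   is a fold for rdh, a percent for pd).
#' @examples
#' b <- simulate_blot_measurements(scenario_preset("rnhAB"),
#'   channel = "s96", timepoints = c(-1, 60), n_replicates = 1, seed = 1)
#' normalize_series(b, rule = "rdh")
#' @export
normalize_series <- function(blots, rule = c("rdh", "pd"),
                             reference_strain = "rnhAB",
                             reference_time = NULL,
                             subtract_background = TRUE) {
  rule <- match.arg(rule)
  ref_t <- reference_time %||% if (rule == "rdh") -1 else 5
  out <- dplyr::mutate(blots,
                       density = band_density(.data$western, .data$southern))
  if (rule == "rdh") {
    refs <- out |>
      dplyr::filter(.data$strain == reference_strain,
                    .data$time_min == ref_t) |>
      dplyr::group_by(.data$batch) |>
      dplyr::summarise(ref_density = mean(.data$density), .groups = "drop")
    missing <- setdiff(unique(out$batch), refs$batch)
    if (length(missing) > 0) {
      abort(sprintf(
        "Batch(es) %s lack the %s reference (strain %s at t = %g).",
        paste(missing, collapse = ", "), rule, reference_strain, ref_t
      ))
    }
    out <- dplyr::inner_join(out, refs, by = "batch") |>
      dplyr::mutate(normalized = .data$density / .data$ref_density) |>
      dplyr::select(-"ref_density")
  } else {
    grouped <- dplyr::group_by(out, .data$batch, .data$strain)
    if (subtract_background) {
      out <- grouped |>
        dplyr::mutate(bg = {
          b <- .data$density[.data$time_min == -1]
          if (length(b) == 0) 0 else mean(b)
        }) |>
        dplyr::ungroup() |>
        dplyr::mutate(density_adj = .data$density - .data$bg)
      n_neg <- sum(out$density_adj < 0)
      if (n_neg > 0) {
        warn(sprintf("%d sub-background densities floored at 0.", n_neg))
        out$density_adj <- pmax(0, out$density_adj)
      }
      out <- dplyr::select(out, -"bg")
    } else {
      out <- dplyr::mutate(dplyr::ungroup(grouped),
                           density_adj = .data$density)
    }
    out <- out |>
      dplyr::group_by(.data$batch, .data$strain) |>
      dplyr::mutate(ref_density = {
        r <- .data$density_adj[.data$time_min == ref_t]
        if (length(r) == 0) NA_real_ else mean(r)
      }) |>
      dplyr::ungroup()
    if (any(is.na(out$ref_density))) {
      bad <- unique(out$batch[is.na(out$ref_density)])
      abort(sprintf("Batch(es) %s lack the pd reference timepoint (t = %g).",
                    paste(bad, collapse = ", "), ref_t))
    }
    out <- out |>
      dplyr::mutate(normalized = 100 * .data$density_adj /
                      .data$ref_density) |>
      dplyr::select(-"ref_density", -"density_adj")
  }
  out
}

#' Fold change of a density time course between two timepoints
#'
#' @param course Tibble with `time_min` and a value column (default
#'   `normalized`); extra grouping columns (`batch`, `strain`) are
#'   averaged over.
#' @param t_from,t_to Timepoints to compare (density at `t_to` over
#'   density at `t_from`).
#' @param value Column to compare.
#' @return Single fold-change ratio.
#' @export
fold_change <- function(course, t_from, t_to, value = "normalized") {
  v_from <- course[[value]][course$time_min == t_from]
  v_to <- course[[value]][course$time_min == t_to]
  if (length(v_from) == 0 || length(v_to) == 0) {
    abort(sprintf("Timepoints %g and %g must both be present.", t_from, t_to))
  }
  if (mean(v_from) == 0) abort("Zero density at `t_from`; fold undefined.")
  mean(v_to) / mean(v_from)
}
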