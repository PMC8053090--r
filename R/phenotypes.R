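# UV survival from spot assays, multiplicative epistasis, and DNA
# synthesis rate recovery.

#' Culture titer from a serial-dilution spot assay
#'
#' Pools spot counts across the countable dilutions (default 3-300
#' colonies per spot) with the Poisson maximum-likelihood estimator
#' total counts / total effective volume, which weights dilutions by
#' their information content (equivalently, inverse-variance). All spots
#' saturated returns a saturated flag with a lower-bound titer; all spots
#' empty returns an extinct flag with an upper-bound titer.
#'
#' @param spots Tibble for one culture/dose: `dilution`, `count`,
#'   `volume_ml` (and optional grouping columns `strain`, `dose`,
#'   `culture`, which are preserved).
#' @param countable Countable window per spot, default `c(3, 300)`.
#' @return Tibble: grouping columns plus `titer` (CFU/ml), `flag`
#'   (`"ok"`, `"saturated"`, `"extinct"`).
#' @examples
#' titer(tibble::tibble(dilution = 3, count = 30, volume_ml = 0.01))
#' @export
titer <- function(spots, countable = c(3, 300)) {
  groups <- intersect(c("strain", "dose", "culture"), names(spots))
  spots |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::reframe({
      cnt <- count; vol <- volume_ml; dil <- dilution
      ok <- cnt >= countable[1] & cnt <= countable[2]
      if (any(ok)) {
        tibble(titer = sum(cnt[ok]) / sum(vol[ok] * 10^(-dil[ok])),
               flag = "ok")
      } else if (all(cnt > countable[2])) {
        # even the highest dilution saturated: lower bound from it
        i <- which.max(dil)
        tibble(titer = countable[2] / (vol[i] * 10^(-dil[i])),
               flag = "saturated")
      } else {
        # nothing countable and some spots empty: upper bound from the
        # lowest dilution (one colony there would have been seen)
        i <- which.min(dil)
        tibble(titer = 1 / (vol[i] * 10^(-dil[i])), flag = "extinct")
      }
    })
}

#' Survival fraction: treated titer over untreated titer
#'
#' @param titer_dose Titer after UV exposure.
#' @param titer_untreated Titer of the untreated culture (> 0).
#' @param flag_dose Optional flag from [titer()]; an `"extinct"` flag
#'   marks the result as an upper bound.
#' @return Tibble: `survival` (capped at 1 with a warning when the ratio
#'   exceeds 1) and `bound` (`"="` or `"<"`).
#' @export
survival <- function(titer_dose, titer_untreated, flag_dose = "ok") {
  if (any(titer_untreated <= 0)) abort("`titer_untreated` must be > 0.")
  s <- titer_dose / titer_untreated
  if (any(s > 1)) {
    warn("Survival ratio above 1 capped at 1.")
    s <- pmin(1, s)
  }
  tibble(survival = s,
         bound = ifelse(flag_dose == "extinct", "<", "="))
}

#' Survival curve from spot assays with Poisson-ratio confidence intervals
#'
#' Titers are estimated per culture, survival per culture as the ratio to
#' the matched untreated culture, and the curve summarises cultures as
#' mean +/- SEM. The CI on the pooled ratio comes from the Poisson ratio
#' (conditional binomial) likelihood, appropriate for small spot counts.
#'
#' @param spots_dose,spots_untreated Spot tibbles from
#'   [simulate_spot_assay()] or of the same shape.
#' @param countable Countable window passed to [titer()].
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `dose`, `survival`, `sem`, `conf_lo`,
#'   `conf_hi`, `n_cultures`.
#' @export
survival_curve_point <- function(spots_dose, spots_untreated,
                                 countable = c(3, 300), conf_level = 0.95) {
  td <- titer(spots_dose, countable)
  tu <- titer(spots_untreated, countable)
  joined <- dplyr::inner_join(td, tu, by = "culture",
                              suffix = c("_dose", "_untx"))
  s <- joined$titer_dose / joined$titer_untx
  # pooled Poisson-ratio CI on total countable counts
  pool_counts <- function(spots) {
    ok <- spots$count >= countable[1] & spots$count <= countable[2]
    c(sum(spots$count[ok]), sum(spots$volume_ml[ok] * 10^(-spots$dilution[ok])))
  }
  a <- pool_counts(spots_dose); b <- pool_counts(spots_untreated)
  ci <- stats::poisson.test(c(round(a[1]), round(b[1])),
                            c(a[2], b[2]), conf.level = conf_level)$conf.int
  tibble(
    dose = spots_dose$dose[1],
    survival = min(1, mean(s)),
    sem = stats::sd(s) / sqrt(length(s)),
    conf_lo = ci[1], conf_hi = min(1, ci[2]),
    n_cultures = length(s)
  )
}

#' Multiplicative epistasis prediction for a double mutant
#'
#' The null expectation for independent defects is that the double
#' mutant's survival equals the product of the single mutants' survivals.
#' The interaction call compares observed to predicted: synergy when the
#' double mutant dies more than `threshold`-fold below the product,
#' epistasis/suppression when it survives more than `threshold`-fold
#' above, multiplicative otherwise.
#'
#' @param survival_a,survival_b Single-mutant survivals in (0, 1].
#' @param observed Optional observed double-mutant survival.
#' @param threshold Fold threshold for the interaction call (default 3).
#' @return Tibble: `predicted` plus, when `observed` is given,
#'   `observed`, `ratio` and `call`.
#' @examples
#' epistasis_predict(0.1, 0.2)  # predicted 0.02
#' @export
epistasis_predict <- function(survival_a, survival_b, observed = NULL,
                              threshold = 3) {
  for (s in list(survival_a, survival_b)) {
    if (any(s <= 0) || any(s > 1)) abort("Survivals must lie in (0, 1].")
  }
  predicted <- survival_a * survival_b
  if (is.null(observed)) return(tibble(predicted = predicted))
  ratio <- observed / predicted
  tibble(
    predicted = predicted, observed = observed, ratio = ratio,
    call = dplyr::case_when(
      ratio < 1 / threshold ~ "synergy",
      ratio > threshold ~ "epistasis/suppression",
      TRUE ~ "multiplicative"
    )
  )
}

#' Dilution-correct and normalize a DNA synthesis rate series
#'
#' Corrected counts are raw counts times the recorded cumulative dilution
#' factor. Mode `"unirradiated"` normalizes to the first measurement;
#' mode `"uv"` normalizes to the value just before UV (time 0).
#'
#' @param series Tibble: `time_min`, `raw_counts`, `cum_dilution`.
#' @param mode `"uv"` or `"unirradiated"`.
#' @return The series plus `corrected` and `normalized` columns.
#' @export
normalize_synthesis <- function(series, mode = c("uv", "unirradiated")) {
  mode <- match.arg(mode)
  if (any(series$cum_dilution < 1) || any(diff(series$cum_dilution) < 0)) {
    abort("`cum_dilution` must be >= 1 and non-decreasing.")
  }
  out <- dplyr::mutate(series,
                       corrected = .data$raw_counts * .data$cum_dilution)
  ref <- if (mode == "uv") {
    v <- out$corrected[out$time_min == 0]
    if (length(v) == 0) abort("Mode 'uv' needs a time 0 measurement.")
    v[1]
  } else {
    out$corrected[which.min(out$time_min)]
  }
  if (ref <= 0) abort("Reference measurement is zero; cannot normalize.")
  dplyr::mutate(out, normalized = .data$corrected / ref)
}
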