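# The 16-fraction lane partition and the RDH x PD co-enrichment statistic.

validate_profile <- function(profile) {
  if (nrow(profile) < 32) abort("A lane profile needs at least 32 samples.")
  if (any(diff(profile$position) <= 0)) {
    abort("Profile positions must be strictly increasing from the well.")
  }
  if (any(profile$signal < 0)) abort("Profile signals must be >= 0.")
  invisible(profile)
}

# Trapezoid integral of a piecewise-linear profile over [a, b].
trapz_window <- function(position, signal, a, b) {
  inner <- position > a & position < b
  xs <- c(a, position[inner], b)
  ys <- approx(position, signal, xout = xs, rule = 2)$y
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Partition a lane profile into equal fractions from well to bottom
#'
#' The span from the well (migration coordinate 0) to the bottom cutoff is
#' split into `n` equal-width windows and the profile signal is integrated
#' (trapezoid rule) in each. Fractions are numbered from the well
#' (fraction 1 = largest fragments).
#'
#' @param profile Lane profile tibble (`position`, `signal`).
#' @param n Number of fractions (default 16).
#' @param bottom_cutoff_kb Fragment size (kb) defining the bottom of the
#'   partitioned span (default 0.35, the midpoint of the 0.2-0.5 kb lane
#'   bottom).
#' @param migration Migration model mapping the cutoff size to a
#'   coordinate.
#' @return Tibble (`fraction`, `signal`) with attributes `span` and `n`;
#'   fraction signals sum to the profile integral over the span.
#' @export
partition_lane <- function(profile, n = 16, bottom_cutoff_kb = 0.35,
                           migration = migration_model()) {
  validate_profile(profile)
  x_cut <- migration$position(bottom_cutoff_kb)
  if (x_cut <= min(profile$position) || x_cut > max(profile$position)) {
    abort("Bottom cutoff lies outside the profile span.")
  }
  bounds <- seq(0, x_cut, length.out = n + 1)
  sig <- vapply(seq_len(n), function(k) {
    trapz_window(profile$position, profile$signal, bounds[k], bounds[k + 1])
  }, numeric(1))
  out <- tibble(fraction = seq_len(n), signal = sig)
  attr(out, "span") <- c(0, x_cut)
  attr(out, "n") <- n
  out
}

check_matching_partition <- function(a, b) {
  if (!identical(attr(a, "n"), attr(b, "n")) ||
      max(abs(attr(a, "span") - attr(b, "span"))) > 1e-9) {
    abort("Fraction series come from different partitions (n or span differ).")
  }
  invisible(TRUE)
}

#' Per-fraction densities: western over Southern fraction signals
#'
#' @param western,southern Matching fraction series from [partition_lane()].
#' @return Tibble (`fraction`, `density`); fractions with zero Southern
#'   signal are flagged missing (`NA`), never zero.
#' @export
fraction_densities <- function(western, southern) {
  check_matching_partition(western, southern)
  dens <- ifelse(southern$signal > 0, western$signal / southern$signal,
                 NA_real_)
  out <- tibble(fraction = western$fraction, density = dens)
  attr(out, "span") <- attr(western, "span")
  attr(out, "n") <- attr(western, "n")
  out
}

#' Normalize per-fraction densities to a reference lane
#'
#' Elementwise ratio of test to reference densities (e.g. 30-min RDH
#' density over log RDH density, or 30-min PD density over 5-min PD
#' density). Missing fractions propagate; a zero reference under a
#' non-zero test is flagged missing with a warning.
#'
#' @param test,reference Density series from [fraction_densities()] on the
#'   same partition.
#' @return Tibble (`fraction`, `ratio`).
#' @export
normalize_fractions <- function(test, reference) {
  check_matching_partition(test, reference)
  bad <- !is.na(test$density) & test$density > 0 &
    (!is.na(reference$density) & reference$density == 0)
  if (any(bad)) {
    warn(sprintf("Zero reference density in fraction(s) %s; flagged missing.",
                 paste(test$fraction[bad], collapse = ", ")))
  }
  ratio <- ifelse(!is.na(reference$density) & reference$density > 0,
                  test$density / reference$density, NA_real_)
  out <- tibble(fraction = test$fraction, ratio = ratio)
  attr(out, "span") <- attr(test, "span")
  attr(out, "n") <- attr(test, "n")
  out
}

#' Map fraction numbers to fragment-size intervals
#'
#' @param migration Migration model.
#' @param n Number of fractions.
#' @param bottom_cutoff_kb Bottom-of-lane size cutoff (kb).
#' @return Tibble (`fraction`, `size_hi_kb`, `size_lo_kb`), monotone
#'   decreasing from the well; under defaults fraction 6 spans 8-10 kb and
#'   fraction 16 ends at the 0.35 kb cutoff.
#' @examples
#' fraction_size_map()[6, ]
#' @export
fraction_size_map <- function(migration = migration_model(), n = 16,
                              bottom_cutoff_kb = 0.35) {
  x_cut <- migration$position(bottom_cutoff_kb)
  bounds <- seq(0, x_cut, length.out = n + 1)
  sizes <- migration$size_kb(bounds)
  if (any(diff(sizes) >= 0)) abort("Migration model is not monotone in size.")
  tibble(fraction = seq_len(n),
         size_hi_kb = sizes[-(n + 1)],
         size_lo_kb = sizes[-1])
}

#' Co-enrichment profile: product of normalized RDH and PD densities
#'
#' The co-enrichment value of a fraction is its normalized RDH density
#' times its normalized PD density. The peak is the argmax (ties resolved
#' to the lowest fraction index, with a warning); the non-peak mean covers
#' the remaining fractions. A fraction missing in either input is missing
#' in the output - never imputed, since the product would fabricate peaks.
#'
#' @param norm_rdh,norm_pd Normalized density series from
#'   [normalize_fractions()] on the same partition.
#' @param migration Migration model used for the per-fraction size
#'   intervals.
#' @return An `uvrdh_coenrichment` object; see [tidy.uvrdh_coenrichment()]
#'   and [glance.uvrdh_coenrichment()].
#' @export
coenrichment_profile <- function(norm_rdh, norm_pd,
                                 migration = migration_model()) {
  check_matching_partition(norm_rdh, norm_pd)
  co <- norm_rdh$ratio * norm_pd$ratio
  n <- attr(norm_rdh, "n")
  sizes <- fraction_size_map(migration, n = n)
  if (all(is.na(co))) abort("All fractions are missing; no profile.")
  peak <- which(co == max(co, na.rm = TRUE))
  if (length(peak) > 1) {
    warn(sprintf("Tied peak in fractions %s; lowest index wins.",
                 paste(peak, collapse = ", ")))
  }
  peak <- peak[1]
  structure(list(
    profile = tibble(
      fraction = norm_rdh$fraction,
      norm_rdh = norm_rdh$ratio,
      norm_pd = norm_pd$ratio,
      coenrichment = co,
      size_hi_kb = sizes$size_hi_kb,
      size_lo_kb = sizes$size_lo_kb
    ),
    peak_fraction = peak,
    peak_value = co[peak],
    non_peak_mean = mean(co[-peak], na.rm = TRUE),
    mean_value = mean(co, na.rm = TRUE)
  ), class = "uvrdh_coenrichment")
}

#' @export
print.uvrdh_coenrichment <- function(x, ...) {
  cat(sprintf(
    "<uvrdh_coenrichment> peak %.3g in fraction #%d (%.2g-%.2g kb); non-peak mean %.3g\n",
    x$peak_value, x$peak_fraction,
    x$profile$size_lo_kb[x$peak_fraction],
    x$profile$size_hi_kb[x$peak_fraction], x$non_peak_mean
  ))
  invisible(x)
}

#' Run the full co-enrichment pipeline on long-format lane profiles
#'
#' Partitions each (replicate, timepoint, channel) profile into fractions,
#' forms RDH (S9.6/Southern) and PD (anti-PD/Southern) densities,
#' normalizes RDH at the test timepoint to the log lane and PD to the
#' 5-min lane, multiplies them, and averages the per-replicate
#' co-enrichment profiles.
#'
#' @param lanes Long tibble with `replicate` (optional), `timepoint`,
#'   `channel` (`southern`, `s96`, `pd`), `position`, `signal` for one
#'   strain.
#' @param time_test Test timepoint (default 30 min).
#' @param time_rdh_ref RDH reference timepoint (default -1, the log lane).
#' @param time_pd_ref PD reference timepoint (default 5 min).
#' @param n,bottom_cutoff_kb,migration Partition settings.
#' @param detection_limit Fractions whose Southern signal falls below this
#'   share of the lane's partitioned Southern total are treated as below
#'   the DNA detection limit and flagged missing (densities there are
#'   ratios of trace signals).
#' @return An `uvrdh_coenrichment` (replicate-averaged).
#' @export
coenrichment_from_lanes <- function(lanes, time_test = 30,
                                    time_rdh_ref = -1, time_pd_ref = 5,
                                    n = 16, bottom_cutoff_kb = 0.35,
                                    migration = migration_model(),
                                    detection_limit = 1e-3) {
  if (!"replicate" %in% names(lanes)) lanes$replicate <- 1L
  reps <- unique(lanes$replicate)
  per_rep <- purrr::map(reps, function(r) {
    one <- dplyr::filter(lanes, .data$replicate == r)
    fs <- function(t, ch) {
      prof <- dplyr::filter(one, .data$timepoint == t, .data$channel == ch)
      if (nrow(prof) == 0) {
        abort(sprintf("Missing lane: timepoint %g, channel %s.", t, ch))
      }
      partition_lane(dplyr::select(prof, "position", "signal"),
                     n = n, bottom_cutoff_kb = bottom_cutoff_kb,
                     migration = migration)
    }
    dens <- function(t, ch) {
      south <- fs(t, "southern")
      d <- fraction_densities(fs(t, ch), south)
      below <- south$signal < detection_limit * sum(south$signal)
      d$density[below] <- NA_real_
      d
    }
    norm_rdh <- normalize_fractions(dens(time_test, "s96"),
                                    dens(time_rdh_ref, "s96"))
    norm_pd <- normalize_fractions(dens(time_test, "pd"),
                                   dens(time_pd_ref, "pd"))
    list(rdh = norm_rdh, pd = norm_pd)
  })
  avg <- function(get) {
    mats <- purrr::map(per_rep, function(p) get(p)$ratio)
    m <- rowMeans(do.call(cbind, mats), na.rm = TRUE)
    out <- get(per_rep[[1]])
    out$ratio <- ifelse(is.nan(m), NA_real_, m)
    out
  }
  coenrichment_profile(avg(function(p) p$rdh), avg(function(p) p$pd),
                       migration = migration)
}
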