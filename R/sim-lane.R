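#' Log-size gel migration model
#'
#' Electrophoretic migration is modeled as log-linear in fragment size:
#' the migration coordinate `x` runs from 0 at the well to 1 at the bottom
#' cutoff, and `size(x) = s_top * (s_bot / s_top)^x`. The defaults
#' (`s_top` 50 kb, `s_bot` 0.35 kb) place 8-10 kb fragments inside the 6th
#' of 16 equal fractions, matching the lane partition used by the
#' co-enrichment analysis.
#'
#' @param s_top_kb Size (kb) migrating at the well (`x = 0`).
#' @param s_bot_kb Size (kb) migrating at the bottom cutoff (`x = 1`).
#' @return A list with functions `position(size_kb)` and `size_kb(x)` plus
#'   the model constants, class `uvrdh_migration`.
#' @examples
#' m <- migration_model()
#' m$position(9)   # lands within fraction 6's span
#' @export
migration_model <- function(s_top_kb = 50, s_bot_kb = 0.35) {
  assert_positive(s_top_kb, "s_top_kb")
  assert_positive(s_bot_kb, "s_bot_kb")
  if (s_bot_kb >= s_top_kb) abort("`s_bot_kb` must be smaller than `s_top_kb`.")
  log_ratio <- log(s_bot_kb / s_top_kb)
  structure(list(
    s_top_kb = s_top_kb,
    s_bot_kb = s_bot_kb,
    position = function(size_kb) {
      # sizes above s_top stay in the well; below s_bot run past the cutoff
      pmax(0, log(size_kb / s_top_kb) / log_ratio)
    },
    size_kb = function(x) s_top_kb * exp(x * log_ratio)
  ), class = "uvrdh_migration")
}

#' Render a gel lane profile from a fragment set
#'
#' Each fragment contributes signal proportional to its channel weight
#' (fragment length for `southern`, hybrid nucleotides for `s96`, PD count
#' for `pd`) at the migration coordinate of its size, spread by a Gaussian
#' band kernel and multiplied by log-normal noise of the stated CV. The
#' profile integral equals the summed (noised) fragment signal times the
#' gain.
#'
#' @param fragments A fragment tibble from [digest()].
#' @param channel `"southern"`, `"s96"` or `"pd"`.
#' @param migration An `uvrdh_migration` model.
#' @param gain Channel gain (> 0).
#' @param noise_cv Per-fragment multiplicative log-normal noise CV.
#' @param band_sd Band spread (migration units).
#' @param n_points Number of profile samples.
#' @param floor_per_nt Non-specific signal added per fragment nucleotide
#'   (used for the anti-PD western's background).
#' @param seed Optional seed.
#' @return A lane profile tibble (`position`, `signal`) with strictly
#'   increasing positions spanning the well (0) past the bottom cutoff (1).
#' @export
render_lane <- function(fragments, channel, migration = migration_model(),
                        gain = 1, noise_cv = 0.15, band_sd = 0.012,
                        n_points = 512, floor_per_nt = 0, seed = NULL) {
  if (nrow(fragments) == 0) abort("`fragments` is empty; nothing to render.")
  assert_positive(gain, "gain")
  w <- switch(channel,
    southern = fragments$length,
    s96 = fragments$rdh_nt,
    pd = fragments$pd_count,
    abort(sprintf("Unknown channel '%s' (southern | s96 | pd).", channel))
  )
  if (floor_per_nt > 0) w <- w + floor_per_nt * fragments$length

  with_local_seed(seed, {
    w <- w * rlnorm_cv(length(w), noise_cv)
    x <- migration$position(fragments$length / 1000)

    lo <- -0.08; hi <- 1.30
    grid <- seq(lo, hi, length.out = n_points)
    dx <- grid[2] - grid[1]
    # bin fragment signal onto the grid, then convolve with the band kernel
    bins <- pmin(pmax(round((x - lo) / dx) + 1, 1), n_points)
    binned <- rep(0, n_points)
    agg <- rowsum(w, bins)
    binned[as.integer(rownames(agg))] <- agg[, 1]
    half <- max(3L, ceiling(4 * band_sd / dx))
    kern <- stats::dnorm(seq(-half, half) * dx, sd = band_sd)
    kern <- kern / sum(kern)
    sig <- stats::filter(c(rep(0, half), binned, rep(0, half)), kern,
                         sides = 2)
    sig <- as.numeric(sig[(half + 1):(half + n_points)])
    sig[is.na(sig)] <- 0
    tibble(position = grid, signal = gain * sig / dx)
  })
}

#' Simulate southern/S9.6/anti-PD lane profiles for a scenario
#'
#' For each replicate and timepoint one pooled digest is drawn (the same
#' DNA sample is split across the gels, as in the assay), then rendered
#' independently per channel with the scenario's gains and noise. The
#' anti-PD channel carries a non-specific background proportional to DNA
#' mass (`pd_floor_frac` of the initial PD signal density).
#'
#' @param sc An `uvrdh_scenario`.
#' @param timepoints Minutes post-UV (`-1` = pre-UV "log").
#' @param enzyme Fragmentation model (default `"HaeII"`).
#' @param channels Channels to render.
#' @param n_replicates Independent experiment replicates.
#' @param n_genomes Genomes pooled per lane.
#' @param seed Optional seed.
#' @return Long tibble: `strain`, `replicate`, `timepoint`, `channel`,
#'   `position`, `signal`.
#' @examples
#' \donttest{
#' lanes <- simulate_lane_profiles(scenario_preset("uvrA"),
#'   timepoints = c(-1, 5, 30), n_replicates = 1, n_genomes = 2, seed = 1)
#' }
#' @export
simulate_lane_profiles <- function(sc, timepoints = c(-1, 5, 30),
                                   enzyme = "HaeII",
                                   channels = c("southern", "s96", "pd"),
                                   n_replicates = 3, n_genomes = 10,
                                   seed = NULL) {
  mig <- migration_model()
  floor_pd <- sc$pd_floor_frac * scenario_pd_count(sc) / sc$genome_length
  grids <- tidyr::expand_grid(replicate = seq_len(n_replicates),
                              timepoint = timepoints)
  purrr::pmap(grids, function(replicate, timepoint) {
    base <- derive_seed(seed, replicate * 1000 + (timepoint + 2) * 7)
    pool <- simulate_digest_pool(sc, timepoint, enzyme,
                                 n_genomes = n_genomes, seed = base)
    purrr::map(channels, function(ch) {
      prof <- render_lane(
        pool, ch, migration = mig, gain = sc$channel_gains[[ch]],
        noise_cv = sc$noise_cv,
        floor_per_nt = if (ch == "pd") floor_pd else 0,
        seed = derive_seed(base, match(ch, c("southern", "s96", "pd")))
      )
      dplyr::mutate(prof, strain = sc$strain, replicate = replicate,
                    timepoint = timepoint, channel = ch, .before = 1)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}
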