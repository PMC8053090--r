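#' Simulate the lesion/hybrid state of one chromosome
#'
#' Draws a single linear genome at a given time post-UV under a scenario's
#' model: pyrimidine dimers (PDs) placed uniformly at a Poisson count set by
#' the dose, each independently "slow" with the scenario's slow-class
#' probability, surviving repair according to two-class exponential decay;
#' plus RNA:DNA hybrid (RDH) intervals. Baseline hybrids are short dispersed
#' stretches; UV-induced hybrids either add more dispersed stretches (RNase
#' H-proficient scenarios) or form full-length structures anchored each at
#' one surviving slow PD (RNase H-deficient scenarios), scaled in total
#' nucleotides by the scenario's per-timepoint fold table.
#'
#' @param sc An `uvrdh_scenario`.
#' @param timepoint Minutes post-UV (`-1` encodes the pre-UV "log" sample).
#' @param seed Optional integer seed for reproducible draws.
#' @return An `uvrdh_chromosome`: a list with `genome_length`, `timepoint`,
#'   `pd` (tibble: `pos`, `class`) and `rdh` (tibble: `start`, `end`,
#'   `anchor`; 0-based half-open intervals, `anchor` is the anchoring slow-PD
#'   position or `NA` for dispersed hybrids).
#' @examples
#' st <- simulate_chromosome_state(scenario_preset("rnhAB"), 30, seed = 1)
#' nrow(st$pd)
#' @export
simulate_chromosome_state <- function(sc, timepoint, seed = NULL) {
  stopifnot(inherits(sc, "uvrdh_scenario"))
  if (sc$dose < 0) abort("`dose` must be non-negative.")
  if (timepoint < 0 && timepoint != -1) {
    abort("`timepoint` must be >= 0 minutes (or -1 for the pre-UV sample).")
  }
  with_local_seed(seed, {
    G <- sc$genome_length
    pre_uv <- timepoint == -1

    # --- PDs ---
    if (pre_uv || sc$dose == 0) {
      pd <- tibble(pos = numeric(), class = character())
    } else {
      n0 <- rpois(1, scenario_pd_count(sc))
      pos <- floor(runif(n0, 0, G))
      cls <- ifelse(runif(n0) < sc$slow_pd_fraction, "slow", "fast")
      p_keep <- ifelse(
        cls == "slow",
        pd_survival_prob(timepoint, sc$slow_half_life, sc$repair_lag_min),
        pd_survival_prob(timepoint, sc$fast_half_life, sc$repair_lag_min)
      )
      keep <- runif(n0) < p_keep
      pd <- tibble(pos = pos[keep], class = cls[keep])
    }

    # --- baseline dispersed hybrids ---
    make_dispersed <- function(total_nt) {
      n <- round(total_nt / sc$rdh_baseline_length)
      if (n <= 0) {
        return(tibble(start = numeric(), end = numeric(), anchor = numeric()))
      }
      len <- rep(sc$rdh_baseline_length, n)
      start <- floor(runif(n, 0, G - len))
      tibble(start = start, end = start + len, anchor = NA_real_)
    }
    rdh <- make_dispersed(sc$rdh_baseline_nt)

    # --- UV-induced hybrids ---
    fold <- rdh_fold_at(sc, timepoint)
    extra_nt <- sc$rdh_baseline_nt * max(0, fold - 1)
    if (!pre_uv && sc$dose > 0 && extra_nt > 0) {
      if (sc$rdh_induced_dispersed) {
        rdh <- dplyr::bind_rows(rdh, make_dispersed(extra_nt))
      } else {
        n_target <- round(extra_nt / sc$rdh_length_mean)
        slow_pos <- pd$pos[pd$class == "slow"]
        n_anchor <- min(n_target, length(slow_pos))
        if (n_anchor < n_target) {
          warn(sprintf(
            "Only %d surviving slow PDs available to anchor %d induced RDHs.",
            length(slow_pos), n_target
          ))
        }
        if (n_anchor > 0) {
          anchors <- sample(slow_pos, n_anchor)
          len <- pmax(200, round(rgamma(
            n_anchor, shape = sc$rdh_length_shape,
            scale = sc$rdh_length_mean / sc$rdh_length_shape
          )))
          # anchor sits uniformly inside its interval
          offset <- floor(runif(n_anchor, 0, len))
          start <- pmax(0, pmin(anchors - offset, G - len))
          rdh <- dplyr::bind_rows(
            rdh, tibble(start = start, end = start + len, anchor = anchors)
          )
        }
      }
    }

    structure(
      list(genome_length = G, timepoint = timepoint, strain = sc$strain,
           pd = pd, rdh = rdh),
      class = "uvrdh_chromosome"
    )
  })
}

#' @export
print.uvrdh_chromosome <- function(x, ...) {
  cat(sprintf(
    "<uvrdh_chromosome> %s, t = %g min: %d PDs (%d slow), %d RDH intervals\n",
    x$strain, x$timepoint, nrow(x$pd), sum(x$pd$class == "slow"), nrow(x$rdh)
  ))
  invisible(x)
}

# Default mean fragment lengths (nt) per fragmentation model.
enzyme_mean_nt <- function(enzyme, shear_mean_nt = 23000) {
  switch(enzyme,
    "uncut" = NULL,
    "sheared" = shear_mean_nt,
    "EcoRI+BamHI" = 4000,
    "HaeII" = 1200,
    "HaeIII" = 600,
    abort(sprintf("Unknown enzyme label '%s'.", enzyme))
  )
}

#' Digest a chromosome state into restriction (or shear) fragments
#'
#' Fragment lengths are drawn from a truncated exponential (0.1-50 kb) with
#' the enzyme's mean spacing and tiled over the genome; PDs and hybrid
#' nucleotides are then assigned to fragments by coordinate. For restriction
#' enzymes, candidate cuts falling inside a hybrid interval (expanded by the
#' anchored structures' protection margin) are suppressed, so hybrid-bearing
#' fragments run long - mechanical shearing (`"sheared"`) is not suppressed.
#' `"uncut"` returns the genome as a single fragment.
#'
#' @param state An `uvrdh_chromosome`.
#' @param enzyme One of `"uncut"`, `"sheared"`, `"EcoRI+BamHI"`, `"HaeII"`,
#'   `"HaeIII"`.
#' @param seed Optional seed.
#' @param mean_nt Optional override of the enzyme's mean fragment length.
#' @param shear_mean_nt Mean shear length used when `enzyme = "sheared"`.
#' @param protection_nt Suppression margin (nt) added around anchored hybrid
#'   intervals for restriction enzymes.
#' @param tail_frac Fraction of the digest drawn from the long
#'   partial-digestion component (genomic digests retain a minor
#'   under-digested tail that smears up the lane).
#' @param tail_mean_nt Mean length of the partial-digestion component.
#' @return A tibble with one row per fragment: `length`, `pd_count`,
#'   `rdh_nt`, plus attributes `enzyme` and `genome_length`. Lesion and mass
#'   totals are conserved exactly.
#' @examples
#' st <- simulate_chromosome_state(scenario_preset("rnhAB"), 30, seed = 1)
#' fr <- digest(st, "HaeII", seed = 2)
#' sum(fr$pd_count) == nrow(st$pd)
#' @export
digest <- function(state, enzyme, seed = NULL, mean_nt = NULL,
                   shear_mean_nt = 23000, protection_nt = 0,
                   tail_frac = 0.006, tail_mean_nt = 30000) {
  stopifnot(inherits(state, "uvrdh_chromosome"))
  mu <- mean_nt %||% enzyme_mean_nt(enzyme, shear_mean_nt)
  G <- state$genome_length

  with_local_seed(seed, {
    if (is.null(mu)) {
      cuts <- numeric()
    } else {
      # over-draw lengths, tile, keep interior cut positions
      draw_lens <- function(n) {
        l <- rexp_trunc(n, mu, 100, 50000)
        if (enzyme != "sheared" && tail_frac > 0) {
          long <- runif(n) < tail_frac
          l[long] <- rexp_trunc(sum(long), tail_mean_nt, 100, 50000)
        }
        l
      }
      n_guess <- ceiling(G / mu * 1.3) + 50
      lens <- draw_lens(n_guess)
      while (sum(lens) < G) lens <- c(lens, draw_lens(n_guess))
      cuts <- cumsum(lens)
      cuts <- cuts[cuts < G]

      if (enzyme != "sheared" && nrow(state$rdh) > 0) {
        margin <- ifelse(is.na(state$rdh$anchor), 0, protection_nt)
        lo <- pmax(0, state$rdh$start - margin)
        hi <- pmin(G, state$rdh$end + margin)
        ord <- order(lo)
        lo <- lo[ord]; hi <- hi[ord]
        # a cut is suppressed if it falls inside any protected interval
        idx <- findInterval(cuts, lo)
        inside <- idx > 0 & cuts < hi[pmax(idx, 1)]
        # handle overlapping intervals: check the running max of hi
        hi_run <- cummax(hi)
        inside <- idx > 0 & cuts < hi_run[pmax(idx, 1)]
        cuts <- cuts[!inside]
      }
    }

    bounds <- c(0, cuts, G)
    lengths <- diff(bounds)
    nfrag <- length(lengths)

    pd_count <- if (nrow(state$pd) > 0) {
      tabulate(findInterval(state$pd$pos, bounds,
                            rightmost.closed = TRUE), nfrag)
    } else {
      rep(0L, nfrag)
    }

    rdh_nt <- rep(0, nfrag)
    if (nrow(state$rdh) > 0) {
      for (i in seq_len(nrow(state$rdh))) {
        s <- max(0, state$rdh$start[i]); e <- min(G, state$rdh$end[i])
        if (e <= s) next
        f1 <- findInterval(s, bounds, rightmost.closed = TRUE)
        f2 <- findInterval(e, bounds, left.open = TRUE,
                           rightmost.closed = TRUE)
        if (f1 == f2) {
          rdh_nt[f1] <- rdh_nt[f1] + (e - s)
        } else {
          for (f in f1:f2) {
            ov <- min(e, bounds[f + 1]) - max(s, bounds[f])
            if (ov > 0) rdh_nt[f] <- rdh_nt[f] + ov
          }
        }
      }
    }

    out <- tibble(length = lengths, pd_count = pd_count, rdh_nt = rdh_nt)
    attr(out, "enzyme") <- enzyme
    attr(out, "genome_length") <- G
    out
  })
}

#' Pool digested fragments from many genomes of one scenario
#'
#' A gel lane or DRIP input contains DNA from a large cell population;
#' pooling several independently drawn genome states stabilises the
#' fragment population the downstream assays see.
#'
#' @param sc An `uvrdh_scenario`.
#' @param timepoint Minutes post-UV (`-1` = pre-UV).
#' @param enzyme Fragmentation model (see [digest()]).
#' @param n_genomes Genomes to pool.
#' @param seed Optional seed.
#' @return A fragment tibble like [digest()]'s, with an `n_genomes`
#'   attribute.
#' @export
simulate_digest_pool <- function(sc, timepoint, enzyme, n_genomes = 10,
                                 seed = NULL) {
  frags <- purrr::map(seq_len(n_genomes), function(g) {
    st <- simulate_chromosome_state(sc, timepoint,
                                    seed = derive_seed(seed, 2 * g))
    digest(st, enzyme, seed = derive_seed(seed, 2 * g + 1),
           shear_mean_nt = sc$shear_mean_nt,
           protection_nt = sc$rdh_protection_nt,
           tail_frac = sc$digest_tail_frac,
           tail_mean_nt = sc$digest_tail_mean_nt)
  })
  out <- dplyr::bind_rows(frags)
  attr(out, "enzyme") <- enzyme
  attr(out, "genome_length") <- sc$genome_length * n_genomes
  attr(out, "n_genomes") <- n_genomes
  out
}
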