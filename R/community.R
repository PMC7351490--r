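## Seeded synthetic microbial-community generator.
##
## Emulates the statistical structure the downstream analysis assumes:
## a lognormal rank-abundance stool profile, cultivation either as isolated
## droplet colonies (no inter-taxon competition, per-droplet carrying
## capacity) or as a shared exponential competition on plates, density-gated
## sorting enrichment, read-level dead-DNA carryover from the inoculum, and
## multinomial sequencing at fixed depth.

#' Synthetic community specification
#'
#' @param n_taxa Number of ASVs (`>= 2`).
#' @param lognormal_mu,lognormal_sigma Log-scale mean and SD of the stool
#'   rank-abundance distribution (`sigma >= 0`; 0 gives a uniform profile).
#' @param growth_rate Per-taxon exponential growth rates (per hour). `NULL`
#'   draws them once, lognormally (`rate_meanlog`, `rate_sdlog`), under the
#'   spec seed; a scalar is recycled.
#' @param growth_success_prob Per-taxon probability that a seeded cell grows
#'   at all. `NULL` draws them once per spec from a U-shaped Beta(0.35,
#'   0.35): most taxa are either essentially unculturable in a given medium
#'   or grow reliably, which is what medium-dependent culturability of gut
#'   anaerobes looks like. A scalar or vector is recycled.
#' @param culture_time Cultivation time in hours.
#' @param n_droplets Droplets generated per run.
#' @param occupancy_lam Poisson mean cells per droplet.
#' @param carrying_capacity Maximum colony size per founder cell in a
#'   droplet (cells); the picoliter-volume cap.
#' @param carryover_fraction True fraction of reads contributed by dead or
#'   nonviable inoculum DNA (the planted `p_nv`), in `[0, 1)`.
#' @param read_depth Reads per sequenced sample.
#' @param seed Generator seed.
#' @param rate_meanlog,rate_sdlog Hyperparameters for drawn growth rates.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(n_taxa = 150L,
                           lognormal_mu = 0, lognormal_sigma = 1.5,
                           growth_rate = NULL,
                           growth_success_prob = NULL,
                           culture_time = 24,
                           n_droplets = 1e4,
                           occupancy_lam = 0.1,
                           carrying_capacity = 500,
                           carryover_fraction = 0.2,
                           read_depth = 1e5,
                           seed = 1L,
                           rate_meanlog = log(0.35), rate_sdlog = 0.45) {
  n_taxa <- as.integer(n_taxa)
  if (n_taxa < 2L) stop_invalid("`n_taxa` must be >= 2")
  if (lognormal_sigma < 0) stop_invalid("`lognormal_sigma` must be >= 0")
  if (carryover_fraction < 0 || carryover_fraction >= 1) {
    stop_invalid("`carryover_fraction` must lie in [0, 1)")
  }
  if (read_depth < 1) stop_invalid("`read_depth` must be >= 1")
  if (occupancy_lam <= 0 || n_droplets < 1 || culture_time <= 0 ||
      carrying_capacity < 1) {
    stop_invalid("growth/droplet parameters must be positive")
  }
  if (is.null(growth_rate)) {
    growth_rate <- with_seed(
      child_seed(seed, 1L),
      stats::rlnorm(n_taxa, rate_meanlog, rate_sdlog)
    )
  }
  growth_rate <- rep_len(growth_rate, n_taxa)
  if (is.null(growth_success_prob)) {
    growth_success_prob <- with_seed(
      child_seed(seed, 5L),
      stats::rbeta(n_taxa, 0.35, 0.35)
    )
  }
  growth_success_prob <- rep_len(growth_success_prob, n_taxa)
  if (any(growth_rate < 0)) stop_invalid("growth rates must be >= 0")
  if (any(growth_success_prob < 0 | growth_success_prob > 1)) {
    stop_invalid("growth success probabilities must lie in [0, 1]")
  }
  structure(
    list(
      n_taxa = n_taxa,
      lognormal_mu = lognormal_mu, lognormal_sigma = lognormal_sigma,
      growth_rate = growth_rate,
      growth_success_prob = growth_success_prob,
      culture_time = culture_time,
      n_droplets = as.integer(n_droplets),
      occupancy_lam = occupancy_lam,
      carrying_capacity = carrying_capacity,
      carryover_fraction = carryover_fraction,
      read_depth = as.integer(read_depth),
      seed = seed,
      asv_ids = sprintf("ASV_%04d", seq_len(n_taxa))
    ),
    class = "community_spec"
  )
}

## normalize a non-negative abundance vector into a community profile
as_profile <- function(x) {
  if (any(x < 0) || sum(x) <= 0) {
    stop_invalid("abundances must be non-negative with positive sum")
  }
  x / sum(x)
}

#' Sample the stool reference profile
#'
#' Proportional abundances drawn as `exp(Normal(mu, sigma))` per taxon and
#' normalized: the classic lognormal rank-abundance structure of a stool
#' community, with many rare taxa for `sigma` around 1.5-2.
#'
#' @param spec A [community_spec()].
#' @return Named proportional-abundance vector summing to 1.
#' @export
sample_stool_profile <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(child_seed(spec$seed, 2L), {
    w <- exp(stats::rnorm(spec$n_taxa, spec$lognormal_mu, spec$lognormal_sigma))
    stats::setNames(as_profile(w), spec$asv_ids)
  })
}

#' Simulate droplet cultivation
#'
#' Loads droplets with Poisson(`occupancy_lam`) cells drawn multinomially
#' from the stool profile. Each founder cell grows independently -- there is
#' no inter-taxon competition inside a droplet run -- to
#' `min(carrying_capacity, exp(rate * time))` with per-taxon success
#' probability. The pooled grown profile is proportional to summed colony
#' biomass.
#'
#' @param stool Stool profile from [sample_stool_profile()].
#' @param spec A [community_spec()].
#' @param seed Optional override of the spec seed for replicate runs.
#' @return A list of class `droplet_culture`: `profile` (pooled grown
#'   profile), `droplet_sizes` (total biomass per droplet, length
#'   `n_droplets`), and `cells` (data frame of founder cells: `droplet`,
#'   `taxon`, `size`).
#' @export
simulate_droplet_culture <- function(stool, spec, seed = spec$seed) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(child_seed(seed, 3L), {
    k <- stats::rpois(spec$n_droplets, spec$occupancy_lam)
    n_cells <- sum(k)
    if (n_cells == 0) stop_invalid("no droplet received a cell; raise `occupancy_lam` or `n_droplets`")
    taxon <- sample.int(spec$n_taxa, n_cells, replace = TRUE, prob = stool)
    droplet <- rep.int(seq_along(k), k)
    grew <- stats::rbinom(n_cells, 1L, spec$growth_success_prob[taxon])
    size <- grew * pmin(
      spec$carrying_capacity,
      exp(spec$growth_rate[taxon] * spec$culture_time)
    )
    pooled <- numeric(spec$n_taxa)
    agg <- rowsum(size, taxon)
    pooled[as.integer(rownames(agg))] <- agg[, 1]
    if (sum(pooled) <= 0) stop_invalid("no colony grew; raise success probabilities")
    droplet_sizes <- numeric(spec$n_droplets)
    dagg <- rowsum(size, droplet)
    droplet_sizes[as.integer(rownames(dagg))] <- dagg[, 1]
    structure(
      list(
        profile = stats::setNames(as_profile(pooled), spec$asv_ids),
        droplet_sizes = droplet_sizes,
        cells = data.frame(droplet = droplet, taxon = taxon, size = size)
      ),
      class = "droplet_culture"
    )
  })
}

#' Simulate plate cultivation (shared exponential competition)
#'
#' The minimal competition model on a shared surface: every taxon grows
#' exponentially from its inoculum share, so the grown profile is
#' proportional to `stool_i * success_i * exp(rate_i * time)` and
#' fast-growers overgrow the rest deterministically.
#'
#' @inheritParams simulate_droplet_culture
#' @return Named grown proportional-abundance vector.
#' @export
simulate_plate_culture <- function(stool, spec) {
  stopifnot(inherits(spec, "community_spec"))
  grown <- stool * spec$growth_success_prob *
    exp(spec$growth_rate * spec$culture_time)
  stats::setNames(as_profile(grown), spec$asv_ids)
}

#' Pool only droplets whose colony size falls in a window
#'
#' Mimics density-gated sorting: droplets whose total colony biomass lies in
#' `[window[1], window[2]]` are kept and pooled. A low window enriches
#' slow-growing taxa.
#'
#' @param culture A `droplet_culture` from [simulate_droplet_culture()].
#' @param window Numeric length-2 inclusive size window; only occupied
#'   droplets (size > 0) are eligible.
#' @param spec The [community_spec()] used to grow the culture.
#' @return Named sorted-pool proportional-abundance vector.
#' @export
simulate_sorting_enrichment <- function(culture, window, spec) {
  stopifnot(inherits(culture, "droplet_culture"))
  if (length(window) != 2 || window[1] > window[2]) {
    stop_invalid("`window` must be c(lo, hi) with lo <= hi")
  }
  sizes <- culture$droplet_sizes
  kept <- which(sizes > 0 & sizes >= window[1] & sizes <= window[2])
  if (length(kept) == 0) {
    stop_invalid("sorting window excludes every occupied droplet",
                 class = "dropcult_empty_selection")
  }
  cells <- culture$cells[culture$cells$droplet %in% kept, ]
  pooled <- numeric(spec$n_taxa)
  agg <- rowsum(cells$size, cells$taxon)
  pooled[as.integer(rownames(agg))] <- agg[, 1]
  stats::setNames(as_profile(pooled), spec$asv_ids)
}

#' Add dead-DNA carryover and sequence to fixed depth
#'
#' Mixes the grown profile with the stool profile at the read level --
#' `(1 - fraction) * grown + fraction * stool` -- reflecting reads from dead
#' or nonviable inoculum DNA, then draws multinomial counts at the given
#' depth.
#'
#' @param grown Grown proportional-abundance vector.
#' @param stool Stool proportional-abundance vector (same taxa).
#' @param carryover_fraction Read fraction contributed by the inoculum, in
#'   `[0, 1]`.
#' @param read_depth Total reads to draw.
#' @param seed RNG seed.
#' @return Named integer count vector summing to `read_depth`.
#' @export
add_carryover_and_sequence <- function(grown, stool, carryover_fraction,
                                       read_depth, seed = 1L) {
  if (length(grown) != length(stool)) {
    stop_invalid("`grown` and `stool` must share taxa")
  }
  if (carryover_fraction < 0 || carryover_fraction > 1) {
    stop_invalid("`carryover_fraction` must lie in [0, 1]")
  }
  mix <- (1 - carryover_fraction) * as_profile(grown) +
    carryover_fraction * as_profile(stool)
  with_seed(child_seed(seed, 4L), {
    counts <- as.integer(stats::rmultinom(1L, as.integer(read_depth), mix))
    stats::setNames(counts, names(grown))
  })
}
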