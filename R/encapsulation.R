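## Poisson statistics of stochastic single-cell encapsulation.
##
## Cells at density rho (cells/mL), diluted D-fold, loaded into droplets of
## volume V (pL) are Poisson distributed across droplets with mean
## lambda = (rho / D) * V / 1e9. The headline quantity is the single-occupancy
## probability p1 = lambda * exp(-lambda): the fraction of droplets that start
## with exactly one live cell.

#' Poisson droplet-occupancy probabilities
#'
#' Computes the expected number of cells per droplet and the probabilities of
#' a droplet containing zero, one, or more than one cell under Poisson
#' loading.
#'
#' @param density Live-cell density of the (undiluted) suspension, in
#'   cells/mL.
#' @param dilution Dilution factor applied before encapsulation
#'   (dimensionless, `>= 1`).
#' @param volume Droplet volume in picoliters.
#'
#' @return An object of class `occupancy_summary`: a list with elements
#'   `lam` (expected cells per droplet), `p0`, `p1` and `p_multi`.
#'
#' @examples
#' # stool aliquot at 0.5e8 cells/mL, diluted 200x, 65 pL droplets
#' poisson_occupancy(0.5e8, 200, 65)
#'
#' @export
poisson_occupancy <- function(density, dilution, volume) {
  if (!is.numeric(density) || density <= 0) {
    stop_invalid("`density` must be a positive number (cells/mL)")
  }
  if (!is.numeric(dilution) || dilution < 1) {
    stop_invalid("`dilution` must be a number >= 1")
  }
  if (!is.numeric(volume) || volume <= 0) {
    stop_invalid("`volume` must be a positive number (pL)")
  }
  lam <- (density / dilution) * (volume / PL_PER_ML)
  p0 <- exp(-lam)
  p1 <- lam * exp(-lam)
  structure(
    list(lam = lam, p0 = p0, p1 = p1, p_multi = 1 - p0 - p1),
    class = "occupancy_summary"
  )
}

#' @export
print.occupancy_summary <- function(x, ...) {
  cat(sprintf(
    "Poisson droplet occupancy (lambda = %.4g)\n  empty: %.4f  single: %.4f  multiple: %.4f\n",
    x$lam, x$p0, x$p1, x$p_multi
  ))
  invisible(x)
}

#' Encapsulation model parameters
#'
#' Bundles the measured cell density (with uncertainty), the dilution factor,
#' the droplet volume range of the generating device, and the emulsion volume
#' of a cultivation run.
#'
#' @param live_density_mean,live_density_sd Live-cell density mean and
#'   standard deviation, cells/mL. `live_density_mean - live_density_sd` must
#'   be positive so the lower extreme of the occupancy range is defined.
#' @param dilution_factor Dilution applied before droplet generation.
#' @param droplet_volume_min,droplet_volume_max Droplet volume range, pL.
#' @param emulsion_volume Total emulsion volume generated, mL.
#'
#' @return An object of class `encapsulation_model`.
#' @export
encapsulation_model <- function(live_density_mean = 1.5e8,
                                live_density_sd = 1.0e8,
                                dilution_factor = 200,
                                droplet_volume_min = 65,
                                droplet_volume_max = 115,
                                emulsion_volume = 1.0) {
  vals <- c(
    live_density_mean, live_density_sd, dilution_factor,
    droplet_volume_min, droplet_volume_max, emulsion_volume
  )
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_invalid("all encapsulation model fields must be positive and finite")
  }
  if (droplet_volume_min > droplet_volume_max) {
    stop_invalid("`droplet_volume_min` must be <= `droplet_volume_max`")
  }
  if (live_density_mean - live_density_sd <= 0) {
    stop_invalid("`live_density_mean - live_density_sd` must be positive")
  }
  structure(
    list(
      live_density_mean = live_density_mean,
      live_density_sd = live_density_sd,
      dilution_factor = dilution_factor,
      droplet_volume_min = droplet_volume_min,
      droplet_volume_max = droplet_volume_max,
      emulsion_volume = emulsion_volume
    ),
    class = "encapsulation_model"
  )
}

#' Single-occupancy range under density uncertainty
#'
#' Evaluates the single-occupancy probability at the parameter extremes of an
#' [encapsulation_model()]: the minimum at (density mean - sd, smallest
#' droplet volume) and the maximum at (density mean + sd, largest droplet
#' volume). With the default parameters (1.5 +/- 1.0e8 cells/mL, 200x
#' dilution, 65-115 pL droplets) the range rounds to 2-12% of droplets
#' starting with a single live cell.
#'
#' @param model An [encapsulation_model()].
#' @return Named numeric vector `c(min = , max = )`, in percent.
#' @export
occupancy_range <- function(model) {
  stopifnot(inherits(model, "encapsulation_model"))
  lo <- poisson_occupancy(
    model$live_density_mean - model$live_density_sd,
    model$dilution_factor, model$droplet_volume_min
  )
  hi <- poisson_occupancy(
    model$live_density_mean + model$live_density_sd,
    model$dilution_factor, model$droplet_volume_max
  )
  c(min = 100 * lo$p1, max = 100 * hi$p1)
}

#' Number of droplets in an emulsion
#'
#' @param emulsion_volume Emulsion volume, mL.
#' @param droplet_volume Droplet volume, pL.
#' @return Integer droplet count (floored; partial droplets do not exist).
#' @examples
#' droplet_count(1.0, 65)  # ~15.4 million
#' @export
droplet_count <- function(emulsion_volume, droplet_volume) {
  if (!is.numeric(emulsion_volume) || emulsion_volume < 0) {
    stop_invalid("`emulsion_volume` must be a non-negative number (mL)")
  }
  if (!is.numeric(droplet_volume) || droplet_volume <= 0) {
    stop_invalid("`droplet_volume` must be a positive number (pL)")
  }
  floor(emulsion_volume * PL_PER_ML / droplet_volume)
}

#' Colony density on an antibiotic screening plate
#'
#' Converts a plating density quoted per square micrometer into cells per
#' square millimeter after dilution. With the defaults (1 cell per 500 um^2,
#' 10,000x dilution) this gives 0.2 cells/mm^2.
#'
#' @param cells_per_um2 Undiluted plating density, cells per square
#'   micrometer.
#' @param dilution Dilution factor applied before plating.
#' @return Cells per square millimeter.
#' @export
plating_density <- function(cells_per_um2 = 1 / 500, dilution = 1e4) {
  if (!is.numeric(cells_per_um2) || cells_per_um2 <= 0) {
    stop_invalid("`cells_per_um2` must be positive")
  }
  if (!is.numeric(dilution) || dilution < 1) {
    stop_invalid("`dilution` must be >= 1")
  }
  # 1 mm^2 = 1e6 um^2
  cells_per_um2 * 1e6 / dilution
}

#' Plates needed to isolate a set of target populations
#'
#' Smallest number of plates such that, with `colonies_per_plate` colonies
#' drawn independently per plate and each colony belonging to target
#' population `i` with probability `target_probs[i]`, every target appears at
#' least once with joint probability at least `confidence`. The model assumes
#' independent multinomial colony sampling; it is a generic dilution-plating
#' model, not a reconstruction of any specific experiment.
#'
#' @param target_probs Per-colony probabilities for each target population,
#'   each in (0, 1].
#' @param colonies_per_plate Countable colonies per plate (`>= 1`).
#' @param confidence Required joint probability of observing every target.
#' @param max_plates Scan cap; exceeded only for pathological inputs.
#' @return Minimum integer number of plates.
#' @examples
#' plates_for_isolation(0.01, colonies_per_plate = 100, confidence = 0.9)
#' @export
plates_for_isolation <- function(target_probs, colonies_per_plate,
                                 confidence = 0.9, max_plates = 1e6) {
  if (length(target_probs) == 0) {
    stop_invalid("`target_probs` must contain at least one probability")
  }
  if (any(!is.finite(target_probs)) || any(target_probs <= 0) ||
      any(target_probs > 1)) {
    stop_invalid("each target probability must lie in (0, 1]")
  }
  if (!is.numeric(colonies_per_plate) || colonies_per_plate < 1) {
    stop_invalid("`colonies_per_plate` must be >= 1")
  }
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1) {
    stop_invalid("`confidence` must lie in (0, 1)")
  }
  for (n in seq_len(max_plates)) {
    m <- n * colonies_per_plate
    # log P(all targets seen) = sum_i log(1 - (1 - p_i)^m), computed in log
    # space to survive tiny probabilities
    log_p <- sum(log1p(-exp(m * log1p(-target_probs))))
    if (log_p >= log(confidence)) {
      return(n)
    }
  }
  stop_invalid("no plate count up to `max_plates` reaches the confidence")
}
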