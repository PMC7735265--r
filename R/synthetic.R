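# Synthetic two-period resurvey, climate-grid and land-use generators.
# Ground truth (per-species niche means and shifts, lapse rate, warming,
# class proportions) is known, so every downstream estimator can be tested
# without the undeposited historical survey data.

#' Define a synthetic resurvey scenario
#'
#' A scenario describes a two-period, elevation-stratified community: each
#' species has a truncated-normal elevation niche in the historical period
#' (\code{true_mean_hist_m}, \code{niche_sd_m}) which translates uphill by
#' \code{true_shift_m} in the modern period. Sampling effort may differ
#' between periods and elevation bins, emulating the unequal intensity of
#' historical and modern surveys.
#'
#' \code{abundance_weight} plays two roles: when \code{effort} is \code{NULL}
#' (equal protocol, no thinning) it is the number of records drawn per species
#' per period; when an effort profile is given it sets the species' share of
#' the per-bin draw pool from which the profile is filled.
#'
#' @param species data frame with columns \code{name}, \code{group}
#'   (\code{bee}/\code{plant}), \code{true_mean_hist_m}, \code{true_shift_m},
#'   \code{niche_sd_m} (> 0), \code{abundance_weight} (> 0)
#' @param binning a [bin_scheme()]; niches are truncated to its range
#' @param effort \code{NULL}, or a list with elements \code{historical} and
#'   \code{modern}, each a vector of exact per-bin record counts of length
#'   \code{binning$n_bins}. Thinning to the profile is exact (a uniform
#'   subsample of the draws), not probabilistic.
#' @param preference bee-by-plant matrix of visitation weights (rownames =
#'   bee names, colnames = plant names); rows need a positive sum.
#'   \code{NULL} means uniform preference over co-occurring plants.
#' @param seed integer seed making the generated records reproducible
#' @return an object of class \code{resurvey_scenario}
#' @export
resurvey_scenario <- function(species, binning, effort = NULL,
                              preference = NULL, seed = 1L) {
  need <- c("name", "group", "true_mean_hist_m", "true_shift_m",
            "niche_sd_m", "abundance_weight")
  missing_cols <- setdiff(need, names(species))
  if (length(missing_cols))
    stop("species table missing column(s): ", paste(missing_cols, collapse = ", "))
  stopifnot(inherits(binning, "bin_scheme"),
            all(species$niche_sd_m > 0),
            all(species$abundance_weight > 0),
            all(species$group %in% c("bee", "plant")),
            !anyDuplicated(species$name))
  if (!is.null(effort)) {
    stopifnot(is.list(effort), all(c("historical", "modern") %in% names(effort)))
    for (p in c("historical", "modern")) {
      if (length(effort[[p]]) != binning$n_bins)
        stop("effort$", p, " must have one count per bin (", binning$n_bins, ")")
      if (any(effort[[p]] < 0)) stop("effort counts must be >= 0")
      if (sum(effort[[p]]) == 0) stop("effort profile all zero for period ", p)
    }
  }
  if (!is.null(preference)) {
    stopifnot(is.matrix(preference), !is.null(rownames(preference)),
              !is.null(colnames(preference)), all(preference >= 0))
    if (any(rowSums(preference) <= 0))
      stop("every preference row must have a positive sum")
  }
  structure(list(species = species, binning = binning, effort = effort,
                 preference = preference, seed = as.integer(seed)),
            class = "resurvey_scenario")
}

# exact inverse-CDF sampler for a normal truncated to [lo, hi]
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic resurvey occurrence table
#'
#' Draws per-species elevations from the scenario's truncated-normal niches
#' (historical mean, plus the true shift in the modern period), optionally
#' thins the pooled draws to an exact per-bin effort profile, and assigns
#' each bee record a visited plant by sampling its preference row restricted
#' to the plants present in the same bin and period. Identical scenarios and
#' seeds give identical tables.
#'
#' When an effort profile requests more records in a bin than were drawn, the
#' available draws in that bin are replicated (sampled with replacement) up
#' to the requested count.
#'
#' @param scenario a [resurvey_scenario()]
#' @return occurrence data frame in the standard schema; attribute
#'   \code{"truth"} carries the scenario's species table
#' @export
generate_resurvey <- function(scenario) {
  stopifnot(inherits(scenario, "resurvey_scenario"))
  sp <- scenario$species
  sch <- scenario$binning
  set.seed(scenario$seed)
  out <- list()
  for (period in c("historical", "modern")) {
    mu <- sp$true_mean_hist_m + if (period == "modern") sp$true_shift_m else 0
    draws <- lapply(seq_len(nrow(sp)), function(i) {
      n_i <- max(1L, as.integer(round(sp$abundance_weight[i])))
      data.frame(taxon = sp$name[i], group = sp$group[i], period = period,
                 elevation_m = round(rtruncnorm(n_i, mu[i], sp$niche_sd_m[i],
                                                sch$lower_m, sch$upper_m), 1),
                 stringsAsFactors = FALSE)
    })
    pool <- do.call(rbind, draws)
    if (!is.null(scenario$effort)) {
      want <- scenario$effort[[period]]
      bins <- assign_bin(pool$elevation_m, sch)
      keep <- integer(0)
      for (b in seq_len(sch$n_bins)) {
        if (want[b] == 0) next
        avail <- which(bins == b)
        if (length(avail) == 0)
          stop(sprintf("effort requests %d records in bin %d (%s) but no draws landed there",
                       want[b], b, period))
        keep <- c(keep,
                  if (length(avail) >= want[b])
                    avail[sample.int(length(avail), want[b])]
                  else
                    c(avail, avail[sample.int(length(avail), want[b] - length(avail),
                                              replace = TRUE)]))
      }
      pool <- pool[sort(keep), , drop = FALSE]
    }
    out[[period]] <- pool
  }
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL
  rec$record_id <- sprintf("s%06d", seq_len(nrow(rec)))
  rec$visited_plant <- NA_character_
  rec$site <- "synthetic"
  rec$n_individuals <- 1L

  # link bee records to co-occurring plants via the preference matrix
  is_bee <- rec$group == "bee"
  plants <- sp$name[sp$group == "plant"]
  if (any(is_bee) && length(plants)) {
    bins <- assign_bin(rec$elevation_m, sch)
    pref <- scenario$preference
    if (is.null(pref)) {
      bees <- sp$name[sp$group == "bee"]
      pref <- matrix(1, length(bees), length(plants),
                     dimnames = list(bees, plants))
    }
    plant_key <- paste(rec$period, bins, rec$taxon)[rec$group == "plant"]
    for (i in which(is_bee)) {
      w <- pref[rec$taxon[i], ]
      cand <- plants[w[plants] > 0 &
                       paste(rec$period[i], bins[i], plants) %in% plant_key]
      if (length(cand))
        rec$visited_plant[i] <- cand[sample.int(length(cand), 1,
                                                prob = pref[rec$taxon[i], cand])]
    }
  }
  rec <- rec[OCC_COLUMNS]
  attr(rec, "truth") <- sp
  rec
}

#' Define a synthetic climate-grid scenario
#'
#' Emulates a gridded temperature product over a mountain buffer: cell
#' temperature is an affine function of elevation (a linear lapse) plus a
#' uniform warming offset in the modern period and Gaussian noise.
#'
#' @param n_cells number of grid cells (each present in both periods)
#' @param elevation_range_m length-2 range over which cell elevations are
#'   drawn uniformly
#' @param lapse_C_per_m temperature lapse rate, negative (default -0.0049
#'   deg C per m, a moist montane August lapse)
#' @param warming_C additive modern-period offset (default 2.1 deg C)
#' @param t0_C sea-level intercept of the historical lapse line
#' @param noise_sd_C standard deviation of cell-level noise (>= 0)
#' @param seed integer seed
#' @return object of class \code{climate_scenario}
#' @export
climate_scenario <- function(n_cells = 356, elevation_range_m = c(1000, 2800),
                             lapse_C_per_m = -0.0049, warming_C = 2.1,
                             t0_C = 22, noise_sd_C = 0.3, seed = 1L) {
  stopifnot(n_cells >= 2, elevation_range_m[1] < elevation_range_m[2],
            lapse_C_per_m < 0, noise_sd_C >= 0)
  structure(list(n_cells = as.integer(n_cells),
                 elevation_range_m = elevation_range_m,
                 lapse_C_per_m = lapse_C_per_m, warming_C = warming_C,
                 t0_C = t0_C, noise_sd_C = noise_sd_C,
                 seed = as.integer(seed)),
            class = "climate_scenario")
}

#' Generate a synthetic climate grid
#'
#' Produces the long-format climate table consumed by the climate analyses:
#' one row per cell and period with August minimum / mean / maximum
#' temperature summaries. Minimum and maximum are the mean offset by -5 and
#' +5 deg C with their own noise; the triple is sorted per row so
#' \code{t_min_C <= t_mean_C <= t_max_C} always holds.
#'
#' @param scenario a [climate_scenario()]
#' @return data frame with columns \code{cell_id,x,y,elevation_m,period,scope,
#'   t_min_C,t_mean_C,t_max_C}
#' @export
generate_climate <- function(scenario) {
  stopifnot(inherits(scenario, "climate_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_cells
  side <- ceiling(sqrt(n))
  elev <- stats::runif(n, scenario$elevation_range_m[1],
                       scenario$elevation_range_m[2])
  base <- scenario$t0_C + scenario$lapse_C_per_m * elev
  rows <- lapply(c("historical", "modern"), function(period) {
    offs <- if (period == "modern") scenario$warming_C else 0
    tri <- cbind(base + offs - 5 + stats::rnorm(n, 0, scenario$noise_sd_C),
                 base + offs     + stats::rnorm(n, 0, scenario$noise_sd_C),
                 base + offs + 5 + stats::rnorm(n, 0, scenario$noise_sd_C))
    tri <- t(apply(tri, 1, sort))
    data.frame(cell_id = sprintf("c%04d", seq_len(n)),
               x = (seq_len(n) - 1) %% side, y = (seq_len(n) - 1) %/% side,
               elevation_m = elev, period = period, scope = "august",
               t_min_C = tri[, 1], t_mean_C = tri[, 2], t_max_C = tri[, 3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic land-use grid
#'
#' Draws categorical land-use labels for grid cells in elevation zones, with
#' per-zone, per-period class proportions — emulating a reconstructed
#' land-cover map sampled at two decades. Cells get uniform elevations within
#' their zone so the table can be re-zoned downstream.
#'
#' @param zones list of length-2 vectors \code{c(lo_m, hi_m)}
#' @param props_by_period list with one element per zone; each element a list
#'   with \code{historical} and \code{modern} named numeric vectors of class
#'   proportions, each summing to 1 (tolerance 1e-9)
#' @param n_cells_per_zone cells per zone per period (recycled over zones)
#' @param seed integer seed
#' @return data frame \code{cell_id,x,y,elevation_m,period,landuse_class}
#' @export
generate_landuse <- function(zones, props_by_period, n_cells_per_zone = 100,
                             seed = 1L) {
  stopifnot(length(zones) == length(props_by_period))
  n_cells_per_zone <- rep_len(n_cells_per_zone, length(zones))
  for (z in seq_along(zones))
    for (p in c("historical", "modern")) {
      pr <- props_by_period[[z]][[p]]
      if (is.null(pr) || is.null(names(pr)))
        stop("props_by_period[[", z, "]]$", p, " must be a named proportion vector")
      if (abs(sum(pr) - 1) > 1e-9)
        stop("proportions for zone ", z, " period ", p, " sum to ", sum(pr),
             ", not 1")
    }
  set.seed(seed)
  rows <- list()
  id <- 0L
  for (z in seq_along(zones)) {
    lo <- zones[[z]][1]; hi <- zones[[z]][2]
    n <- n_cells_per_zone[z]
    elev <- stats::runif(n, lo, hi)
    for (p in c("historical", "modern")) {
      pr <- props_by_period[[z]][[p]]
      cls <- names(pr)[sample.int(length(pr), n, replace = TRUE, prob = pr)]
      rows[[length(rows) + 1L]] <-
        data.frame(cell_id = sprintf("lu%05d", id + seq_len(n)),
                   x = seq_len(n), y = z, elevation_m = elev, period = p,
                   landuse_class = cls, stringsAsFactors = FALSE)
    }
    id <- id + n
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
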