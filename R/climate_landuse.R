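# Climate context for the resurvey comparison: decadal aggregation of
# gridded temperatures, paired period tests, the warming trend, conversion
# of warming into an equivalent uphill displacement of isotherms via the
# temperature lapse rate, per-species occupied-climate-range tests, and
# elevation-zone land-use change tests.

climate_var_col <- function(variable = c("mean", "min", "max")) {
  variable <- match.arg(variable)
  paste0("t_", variable, "_C")
}

#' Decadal mean of yearly climate series
#'
#' Aggregates a long-format yearly table (one row per cell and year) to one
#' summary per cell: the arithmetic mean over the years of the decade that
#' are present. Cells with no year in range are excluded and reported via
#' the \code{"excluded_cells"} attribute; cells with a partial decade are
#' averaged over the years present and flagged in \code{n_years}.
#'
#' @param series data frame with columns \code{cell_id}, \code{year} and one
#'   or more value columns (e.g. \code{t_min_C,t_mean_C,t_max_C})
#' @param decade length-2 inclusive year range, e.g. \code{c(1900, 1910)}
#' @param value_cols value columns to aggregate; default every numeric
#'   column except \code{year}
#' @return data frame with \code{cell_id}, \code{n_years} and the aggregated
#'   value columns
#' @export
decadal_mean <- function(series, decade, value_cols = NULL) {
  stopifnot(all(c("cell_id", "year") %in% names(series)),
            length(decade) == 2, decade[1] <= decade[2])
  if (is.null(value_cols))
    value_cols <- setdiff(names(series)[vapply(series, is.numeric, logical(1))],
                          c("year", "x", "y", "elevation_m"))
  if (length(value_cols) == 0) stop("no value columns to aggregate")
  all_cells <- unique(series$cell_id)
  sel <- series$year >= decade[1] & series$year <= decade[2]
  sub <- series[sel, , drop = FALSE]
  excluded <- setdiff(all_cells, unique(sub$cell_id))
  if (length(excluded))
    warning(length(excluded), " cell(s) have no year in [", decade[1], ", ",
            decade[2], "] and were excluded")
  if (nrow(sub) == 0) stop("no observations in the requested decade")
  out <- stats::aggregate(sub[value_cols], by = list(cell_id = sub$cell_id),
                          FUN = mean)
  ny <- stats::aggregate(sub$year, by = list(cell_id = sub$cell_id),
                         FUN = function(y) length(unique(y)))
  out$n_years <- ny$x[match(out$cell_id, ny$cell_id)]
  out <- out[c("cell_id", "n_years", value_cols)]
  attr(out, "excluded_cells") <- excluded
  out
}

#' Paired two-period temperature test
#'
#' Pairs every grid cell's historical and modern summaries and applies a
#' two-sided paired t-test (computed as a one-sample t on the per-cell
#' modern-minus-historical differences, which is the identical statistic)
#' with \code{df = n_cells - 1}.
#'
#' @param cells climate data frame with \code{cell_id}, \code{period} and
#'   temperature columns (both periods for every cell)
#' @param variable \code{"mean"}, \code{"min"} or \code{"max"}
#' @return list: \code{variable, mean_diff_C, statistic, df, p_value, n_cells}
#' @export
paired_period_test <- function(cells, variable = c("mean", "min", "max")) {
  col <- climate_var_col(variable)
  h <- cells[cells$period == "historical", , drop = FALSE]
  m <- cells[cells$period == "modern", , drop = FALSE]
  unmatched <- c(setdiff(h$cell_id, m$cell_id), setdiff(m$cell_id, h$cell_id))
  if (length(unmatched))
    stop("cell(s) present in only one period: ",
         paste(utils::head(unmatched, 10), collapse = ", "))
  d <- m[[col]][match(h$cell_id, m$cell_id)] - h[[col]]
  degenerate <- stats::sd(d) / sqrt(length(d)) <=
    10 * .Machine$double.eps * abs(mean(d))
  if (degenerate) {
    # noiseless uniform offset: t underflows every printable floor
    return(list(variable = match.arg(variable), mean_diff_C = mean(d),
                statistic = if (mean(d) == 0) 0 else Inf, df = length(d) - 1,
                p_value = if (mean(d) == 0) 1 else 0, n_cells = length(d)))
  }
  tt <- stats::t.test(d, mu = 0)
  list(variable = match.arg(variable), mean_diff_C = mean(d),
       statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, n_cells = length(d))
}

#' Warming trend over years
#'
#' OLS slope of a temperature series on year. Passing one row per year fits
#' the mean series; passing one row per cell and year pools cells.
#'
#' @param series data frame with columns \code{year} and \code{value}
#' @return list: \code{slope_C_per_year, se, p_value, n,
#'   total_change_C} (slope times the year span)
#' @export
warming_trend <- function(series) {
  stopifnot(all(c("year", "value") %in% names(series)))
  if (length(unique(series$year)) < 10)
    stop("need at least 10 distinct years, got ", length(unique(series$year)))
  fit <- stats::lm(value ~ year, data = series)
  co <- summary(fit)$coefficients
  span <- diff(range(series$year))
  list(slope_C_per_year = co["year", "Estimate"], se = co["year", "Std. Error"],
       p_value = co["year", "Pr(>|t|)"], n = nrow(series),
       total_change_C = co["year", "Estimate"] * span)
}

#' Equivalent-elevation displacement of a temperature isotherm
#'
#' Converts the warming between periods into the uphill distance by which
#' the historical temperature regime has moved: positive displacement means
#' the historical isotherm is now found higher. Two reconstructions are
#' offered (the underlying survey publication does not state its method):
#' \describe{
#'   \item{\code{lapse_ratio}}{estimate the lapse rate \eqn{b} (deg C/m, OLS
#'     of the modern summary on elevation), then per cell
#'     \eqn{d_i = \Delta T_i / (-b)} where \eqn{\Delta T_i} is the cell's
#'     modern-minus-historical difference.}
#'   \item{\code{isotherm_match}}{for each cell, find the elevation at which
#'     the fitted modern lapse line equals the cell's historical
#'     temperature; the displacement is that elevation minus the cell's.}
#' }
#' Both give \eqn{\Delta T / |b|} exactly on a noiseless grid.
#'
#' @param cells climate data frame (both periods, matched \code{cell_id}s)
#' @param variable \code{"mean"}, \code{"min"} or \code{"max"}
#' @param method \code{"lapse_ratio"} (default) or \code{"isotherm_match"}
#' @return list: \code{variable, displacement_mean_m, displacement_sd_m,
#'   lapse_C_per_m, method, n_cells}
#' @export
equivalent_elevation <- function(cells, variable = c("mean", "min", "max"),
                                 method = c("lapse_ratio", "isotherm_match")) {
  method <- match.arg(method)
  col <- climate_var_col(variable)
  h <- cells[cells$period == "historical", , drop = FALSE]
  m <- cells[cells$period == "modern", , drop = FALSE]
  if (nrow(h) == 0 || nrow(m) == 0) stop("both periods required")
  if (diff(range(cells$elevation_m)) < 300)
    stop("elevation span below 300 m; lapse rate not identifiable")
  m <- m[match(h$cell_id, m$cell_id), , drop = FALSE]
  if (anyNA(m$cell_id)) stop("unmatched cells between periods")
  fit <- stats::lm(m[[col]] ~ m$elevation_m)
  b <- unname(stats::coef(fit)[2])
  if (abs(b) < 1e-4)
    stop("no meaningful elevation-temperature gradient (|lapse| < 1e-4 C/m)")
  d <- switch(method,
    lapse_ratio = (m[[col]] - h[[col]]) / (-b),
    isotherm_match = {
      a <- unname(stats::coef(fit)[1])
      (h[[col]] - a) / b - h$elevation_m
    })
  list(variable = match.arg(variable), displacement_mean_m = mean(d),
       displacement_sd_m = stats::sd(d), lapse_C_per_m = b, method = method,
       n_cells = length(d))
}

#' Per-species occupied-climate-range test
#'
#' For each shared species, compares the temperatures of its occupied
#' elevations between periods with a Kruskal--Wallis rank test (two groups).
#' A record's temperature is, by default, read off the period's fitted lapse
#' line at the record's elevation (grid-resolution independent); the
#' \code{nearest} mode snaps to the period's nearest cell by elevation
#' instead, warning about records outside the grid's elevation hull.
#'
#' @param records occurrence data frame
#' @param cells climate data frame (both periods)
#' @param variable \code{"mean"}, \code{"min"} or \code{"max"}
#' @param taxa species to test; default those with >= 2 records per period
#' @param mode \code{"lapse"} (default) or \code{"nearest"}
#' @return data frame: \code{taxon, n_hist, n_mod, mean_temp_hist_C,
#'   mean_temp_mod_C, mean_diff_C, statistic, df, p_value}
#' @export
occupied_climate_test <- function(records, cells,
                                  variable = c("mean", "min", "max"),
                                  taxa = NULL, mode = c("lapse", "nearest")) {
  mode <- match.arg(mode)
  col <- climate_var_col(variable)
  if (is.null(taxa)) taxa <- filter_shared_species(records, 2)
  if (length(taxa) == 0) stop("no shared taxa to test")
  ind <- expand_individuals(records[records$taxon %in% taxa, , drop = FALSE])
  temp_at <- function(period, elev) {
    cc <- cells[cells$period == period, , drop = FALSE]
    if (mode == "lapse") {
      fit <- stats::lm(cc[[col]] ~ cc$elevation_m)
      unname(stats::coef(fit)[1] + stats::coef(fit)[2] * elev)
    } else {
      hull <- range(cc$elevation_m)
      outside <- elev < hull[1] | elev > hull[2]
      if (any(outside))
        warning(sum(outside), " record(s) outside the grid's elevation hull [",
                round(hull[1]), ", ", round(hull[2]),
                "] m; nearest cell used (max distance ",
                round(max(pmax(hull[1] - elev, elev - hull[2], 0))), " m)")
      cc[[col]][vapply(elev, function(e) which.min(abs(cc$elevation_m - e)),
                       integer(1))]
    }
  }
  ind$temp <- NA_real_
  for (p in c("historical", "modern")) {
    sel <- ind$period == p
    ind$temp[sel] <- temp_at(p, ind$elevation_m[sel])
  }
  rows <- lapply(sort(taxa), function(tx) {
    s <- ind[ind$taxon == tx, , drop = FALSE]
    th <- s$temp[s$period == "historical"]
    tm <- s$temp[s$period == "modern"]
    kw <- stats::kruskal.test(list(th, tm))
    data.frame(taxon = tx, n_hist = length(th), n_mod = length(tm),
               mean_temp_hist_C = mean(th), mean_temp_mod_C = mean(tm),
               mean_diff_C = mean(tm) - mean(th),
               statistic = unname(kw$statistic), df = unname(kw$parameter),
               p_value = kw$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Land-use change tests by elevation zone
#'
#' For each elevation zone, cross-tabulates land-use class counts by period
#' and applies a 2-by-k chi-squared test on the raw cell counts (no
#' continuity correction). Classes absent from both periods in a zone are
#' dropped, so \code{df} is the number of observed classes minus 1.
#'
#' @param grid land-use data frame: \code{cell_id, elevation_m, period,
#'   landuse_class}
#' @param zones list of length-2 vectors \code{c(lo_m, hi_m)}; zones are
#'   half-open \code{[lo, hi)} except the last, closed at its top
#' @return data frame of class \code{zone_landuse}: \code{zone_lo, zone_hi,
#'   chi2, df, p_value, n_hist, n_mod}; the per-zone contingency tables are
#'   attached as attribute \code{"tables"}
#' @export
landuse_change_test <- function(grid, zones) {
  stopifnot(all(c("elevation_m", "period", "landuse_class") %in% names(grid)))
  rows <- list()
  tabs <- list()
  for (z in seq_along(zones)) {
    lo <- zones[[z]][1]; hi <- zones[[z]][2]
    closed_top <- z == length(zones)
    sel <- grid$elevation_m >= lo &
      (if (closed_top) grid$elevation_m <= hi else grid$elevation_m < hi)
    sub <- grid[sel, , drop = FALSE]
    present <- unique(sub$period)
    if (!all(c("historical", "modern") %in% present))
      stop(sprintf("zone [%g, %g] has cells for only one period", lo, hi))
    tab <- table(factor(sub$period, levels = c("historical", "modern")),
                 sub$landuse_class)
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    ct <- if (ncol(tab) < 2)
      list(statistic = c(0), parameter = c(0), p.value = 1)
    else
      suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    rows[[z]] <- data.frame(zone_lo = lo, zone_hi = hi,
                            chi2 = unname(ct$statistic),
                            df = unname(ct$parameter),
                            p_value = ct$p.value,
                            n_hist = sum(tab["historical", ]),
                            n_mod = sum(tab["modern", ]))
    tabs[[z]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "tables") <- tabs
  class(out) <- c("zone_landuse", "data.frame")
  out
}
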