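# Linking pollinator elevation shifts to the shifts of the plants they
# visit, weighted by interaction frequency, plus elevation-resolved
# visitation profiles.

#' Count bee-plant interaction frequencies
#'
#' Tallies bee visits to each plant per period from the \code{visited_plant}
#' field of bee records (weighted by \code{n_individuals}). Pairs never
#' observed are absent from the result.
#'
#' @param records occurrence data frame
#' @return data frame \code{bee, plant, n_visits_hist, n_visits_mod}; empty
#'   (with a warning) when no record carries a visited plant
#' @export
interaction_weights <- function(records) {
  bees <- records[records$group == "bee" & !is.na(records$visited_plant), ,
                  drop = FALSE]
  if (nrow(bees) == 0) {
    warning("no bee record carries a visited_plant; returning empty weights")
    return(data.frame(bee = character(), plant = character(),
                      n_visits_hist = integer(), n_visits_mod = integer()))
  }
  n <- if ("n_individuals" %in% names(bees)) bees$n_individuals else
    rep(1L, nrow(bees))
  agg <- stats::aggregate(n, by = list(bee = bees$taxon,
                                       plant = bees$visited_plant,
                                       period = bees$period), FUN = sum)
  out <- stats::reshape(agg, idvar = c("bee", "plant"), timevar = "period",
                        direction = "wide")
  names(out) <- sub("^x\\.historical$", "n_visits_hist", names(out))
  names(out) <- sub("^x\\.modern$", "n_visits_mod", names(out))
  for (col in c("n_visits_hist", "n_visits_mod")) {
    if (!col %in% names(out)) out[[col]] <- 0L
    out[[col]][is.na(out[[col]])] <- 0L
  }
  out <- out[order(out$bee, out$plant), c("bee", "plant", "n_visits_hist",
                                          "n_visits_mod")]
  rownames(out) <- NULL
  out
}

#' Interaction-weighted mean shift of a bee's visited plants
#'
#' Computes the mean elevation shift of the plants a bee visits, weighted by
#' visitation frequency: \eqn{\sum_p w_p s_p / \sum_p w_p} over plants with a
#' defined shift estimate, where by default \eqn{w_p} pools both periods'
#' visit counts. Plants lacking an estimate are excluded and counted.
#'
#' @param bee bee taxon name
#' @param weights output of [interaction_weights()]
#' @param plant_estimates \code{shift_estimates} data frame for plants
#' @param weight_period which period's visit counts weight the mean:
#'   \code{"both"} (default), \code{"historical"} or \code{"modern"}
#' @return list: \code{bee}, \code{weighted_shift_m}, \code{n_plants_used},
#'   \code{n_plants_excluded}, \code{plants_used} (data frame of plant,
#'   weight, shift_m)
#' @export
weighted_plant_shift <- function(bee, weights, plant_estimates,
                                 weight_period = c("both", "historical",
                                                   "modern")) {
  weight_period <- match.arg(weight_period)
  w <- weights[weights$bee == bee, , drop = FALSE]
  if (nrow(w) == 0) stop("no interaction weights for bee ", bee)
  w$weight <- switch(weight_period,
                     both = w$n_visits_hist + w$n_visits_mod,
                     historical = w$n_visits_hist,
                     modern = w$n_visits_mod)
  w <- w[w$weight > 0, , drop = FALSE]
  m <- match(w$plant, plant_estimates$taxon)
  w$shift_m <- plant_estimates$shift_m[m]
  usable <- !is.na(w$shift_m)
  if (!any(usable))
    stop("no visited plant of ", bee, " has a defined shift estimate")
  used <- w[usable, , drop = FALSE]
  list(bee = bee,
       weighted_shift_m = sum(used$weight * used$shift_m) / sum(used$weight),
       n_plants_used = nrow(used),
       n_plants_excluded = sum(!usable),
       plants_used = used[c("plant", "weight", "shift_m")])
}

#' Regress bee shifts on the weighted shifts of their visited plants
#'
#' Assembles, for every bee with a defined shift estimate and at least one
#' visited plant with a defined estimate, the pair (bee shift, interaction-
#' weighted plant shift), and fits an unweighted ordinary least squares
#' regression of bee shift on plant shift. Residuals from the 1:1 line
#' (equal shifts) and a leave-one-out slope diagnostic — flagging pairs
#' whose removal flips the slope's sign — are reported alongside.
#'
#' @param bee_estimates \code{shift_estimates} for bees
#' @param weights output of [interaction_weights()]
#' @param plant_estimates \code{shift_estimates} for plants
#' @param weight_period passed to [weighted_plant_shift()]
#' @return list of class \code{shift_linkage}: \code{pairs} (data frame
#'   \code{bee, shift_m, weighted_plant_shift_m, n_plants_used,
#'   resid_1to1_m, loo_slope}), \code{slope}, \code{intercept},
#'   \code{r_squared}, \code{p_value}, \code{n},
#'   \code{sign_sensitive_to} (bees whose removal flips the slope sign),
#'   \code{excluded_bees}
#' @export
shift_regression <- function(bee_estimates, weights, plant_estimates,
                             weight_period = "both") {
  pairs <- list()
  excluded <- character()
  for (i in seq_len(nrow(bee_estimates))) {
    bee <- bee_estimates$taxon[i]
    if (is.na(bee_estimates$shift_m[i]) || !bee %in% weights$bee) {
      excluded <- c(excluded, bee)
      next
    }
    wps <- tryCatch(weighted_plant_shift(bee, weights, plant_estimates,
                                         weight_period),
                    error = function(e) NULL)
    if (is.null(wps)) {
      excluded <- c(excluded, bee)
      next
    }
    pairs[[length(pairs) + 1L]] <-
      data.frame(bee = bee, shift_m = bee_estimates$shift_m[i],
                 weighted_plant_shift_m = wps$weighted_shift_m,
                 n_plants_used = wps$n_plants_used, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  fit_pairs(pairs, excluded)
}

# OLS core shared by shift_regression() and simulation tests
fit_pairs <- function(pairs, excluded_bees = character()) {
  if (is.null(pairs) || nrow(pairs) < 3)
    stop("need at least 3 (bee, plant) shift pairs, got ",
         if (is.null(pairs)) 0 else nrow(pairs))
  if (stats::var(pairs$weighted_plant_shift_m) == 0)
    stop("zero variance in weighted plant shifts; regression undefined")
  fit <- stats::lm(shift_m ~ weighted_plant_shift_m, data = pairs)
  sm <- summary(fit)
  pairs$resid_1to1_m <- pairs$shift_m - pairs$weighted_plant_shift_m
  pairs$loo_slope <- vapply(seq_len(nrow(pairs)), function(i) {
    if (nrow(pairs) <= 3) return(NA_real_)
    if (stats::var(pairs$weighted_plant_shift_m[-i]) == 0) return(NA_real_)
    unname(stats::coef(stats::lm(shift_m ~ weighted_plant_shift_m,
                                 data = pairs[-i, ]))[2])
  }, numeric(1))
  slope <- unname(stats::coef(fit)[2])
  flips <- !is.na(pairs$loo_slope) & sign(pairs$loo_slope) != sign(slope)
  res <- list(pairs = pairs,
              slope = slope,
              intercept = unname(stats::coef(fit)[1]),
              r_squared = sm$r.squared,
              p_value = sm$coefficients[2, 4],
              n = nrow(pairs),
              sign_sensitive_to = pairs$bee[flips],
              excluded_bees = excluded_bees)
  class(res) <- "shift_linkage"
  res
}

#' @export
print.shift_linkage <- function(x, ...) {
  cat(sprintf("Bee shift ~ weighted plant shift (n = %d)\n", x$n))
  cat(sprintf("  slope = %.3g, intercept = %.3g, R^2 = %.3g, p = %.3g\n",
              x$slope, x$intercept, x$r_squared, x$p_value))
  if (length(x$sign_sensitive_to))
    cat("  slope sign depends on: ",
        paste(x$sign_sensitive_to, collapse = ", "), "\n")
  if (length(x$excluded_bees))
    cat("  excluded (no usable plant estimates): ",
        paste(x$excluded_bees, collapse = ", "), "\n")
  invisible(x)
}

#' Elevation-resolved visitation profile of a plant
#'
#' For one plant, tabulates which bee species account for its visits in each
#' elevation bin and period, as proportions that sum to 1 over bees within
#' every occupied bin. Bins with no visits are absent, not zero-filled; the
#' per-bin total visit count is reported alongside the proportions.
#'
#' @param plant plant taxon name
#' @param records occurrence data frame (bee records with
#'   \code{visited_plant})
#' @param scheme a [bin_scheme()]
#' @return long-format data frame \code{plant, period, bin, bin_lo, bin_hi,
#'   bee, visits, bin_total, proportion}
#' @export
visitation_profile <- function(plant, records, scheme) {
  v <- records[records$group == "bee" & !is.na(records$visited_plant) &
                 records$visited_plant == plant, , drop = FALSE]
  if (nrow(v) == 0) stop("no visit records for plant ", plant)
  n <- if ("n_individuals" %in% names(v)) v$n_individuals else rep(1L, nrow(v))
  bin <- assign_bin(v$elevation_m, scheme)
  agg <- stats::aggregate(n, by = list(period = v$period, bin = bin,
                                       bee = v$taxon), FUN = sum)
  names(agg)[names(agg) == "x"] <- "visits"
  totals <- stats::aggregate(agg$visits, by = list(period = agg$period,
                                                   bin = agg$bin), FUN = sum)
  m <- match(paste(agg$period, agg$bin), paste(totals$period, totals$bin))
  edges <- bin_edges(scheme)
  out <- data.frame(plant = plant, period = agg$period, bin = agg$bin,
                    bin_lo = edges$lo_m[agg$bin], bin_hi = edges$hi_m[agg$bin],
                    bee = agg$bee, visits = agg$visits,
                    bin_total = totals$x[m],
                    proportion = agg$visits / totals$x[m],
                    stringsAsFactors = FALSE)
  out <- out[order(out$period, out$bin, out$bee), ]
  rownames(out) <- NULL
  out
}

#' The most-visited plants across both periods
#'
#' @param weights output of [interaction_weights()]
#' @param n how many plants
#' @return character vector of plant names, by total visits, decreasing
#' @export
top_visited_plants <- function(weights, n = 3) {
  tot <- tapply(weights$n_visits_hist + weights$n_visits_mod, weights$plant,
                sum)
  names(sort(tot, decreasing = TRUE))[seq_len(min(n, length(tot)))]
}
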