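# Effort-balanced estimation of per-species elevational range shifts.
#
# The comparison of mean elevations between two survey periods is biased
# when sampling effort is distributed differently over the gradient. The
# estimator removes this bias by stratifying records into elevation bins
# and, within each bin, subsampling the better-sampled period down to the
# other period's count (without replacement), so both periods contribute
# equal effort per bin. Species mean elevations are computed on the balanced
# subset; the procedure is repeated (default 1000 replicates) and per-species
# differences are averaged.

# expand record rows into individuals (n_individuals copies of each row)
expand_individuals <- function(records) {
  n <- if ("n_individuals" %in% names(records)) records$n_individuals else
    rep(1L, nrow(records))
  records[rep(seq_len(nrow(records)), n), , drop = FALSE]
}

#' One balanced subsample of a two-period record set
#'
#' Within each elevation bin, keeps every individual of the period with the
#' smaller count and a uniform random subset without replacement, of exactly
#' that count, from the other period. Bins occupied in only one period
#' contribute nothing from either period. Records are expanded to individuals
#' (\code{n_individuals} copies) before balancing, so the resampling unit is
#' the individual observation.
#'
#' Uses the current RNG state; call \code{set.seed()} first for
#' reproducibility.
#'
#' @param records occurrence data frame for one taxon group, both periods
#' @param scheme a [bin_scheme()] covering the records' elevations
#' @return the balanced subset as an occurrence data frame (one row per
#'   individual, \code{n_individuals} set to 1)
#' @export
balanced_replicate <- function(records, scheme) {
  ind <- expand_individuals(records)
  ind$n_individuals <- 1L
  bins <- assign_bin(ind$elevation_m, scheme)
  is_hist <- ind$period == "historical"
  keep <- integer(0)
  for (b in unique(bins)) {
    h <- which(bins == b & is_hist)
    m <- which(bins == b & !is_hist)
    if (length(h) == 0 || length(m) == 0) next
    k <- min(length(h), length(m))
    keep <- c(keep,
              if (length(h) == k) h else h[sample.int(length(h), k)],
              if (length(m) == k) m else m[sample.int(length(m), k)])
  }
  ind[sort(keep), , drop = FALSE]
}

#' Estimate per-species elevation shifts by balanced resampling
#'
#' For each of \code{n_replicates} replicates, draws one effort-balanced
#' subset of the whole group's records (community-level balancing by
#' default), computes every taxon's mean elevation per period over its
#' records in the subset, and records the modern-minus-historical
#' difference. Replicates in which a taxon has no records in one period are
#' skipped for that taxon and counted. The estimate is the average
#' per-replicate difference; its spread over replicates is reported as
#' \code{replicate_sd}.
#'
#' A taxon with zero usable replicates is returned with \code{NA} estimates
#' (undefined), never silently as 0.
#'
#' @param records occurrence data frame for one taxon group (bees or plants)
#' @param scheme a [bin_scheme()]
#' @param taxa taxa to estimate; default [filter_shared_species()] with
#'   \code{min_per_period = 2}
#' @param n_replicates number of balanced replicates (default 1000)
#' @param seed optional integer seed
#' @param balance \code{"community"} pools all of the group's records per bin
#'   before balancing (so rarer species ride on the community effort
#'   profile); \code{"species"} balances each species' own records per bin —
#'   a sensitivity mode
#' @param min_per_period passed to [filter_shared_species()] when \code{taxa}
#'   is \code{NULL}
#' @return data frame of class \code{shift_estimates}, one row per taxon:
#'   \code{taxon, n_hist, n_mod} (observed individuals),
#'   \code{mean_hist, mean_mod} (resampled means, m),
#'   \code{shift_m}, \code{replicate_sd},
#'   \code{n_replicates_used, n_replicates_skipped},
#'   \code{min_hist, max_hist, min_mod, max_mod} (observed extremes)
#' @examples
#' sch <- bin_scheme(1000, 2200)
#' sp <- data.frame(name = "b1", group = "bee", true_mean_hist_m = 1500,
#'                  true_shift_m = 150, niche_sd_m = 120, abundance_weight = 80)
#' occ <- generate_resurvey(resurvey_scenario(sp, bin_scheme(1000, 2200), seed = 7))
#' estimate_shifts(occ, sch, taxa = "b1", n_replicates = 200, seed = 1)
#' @export
estimate_shifts <- function(records, scheme, taxa = NULL, n_replicates = 1000,
                            seed = NULL, balance = c("community", "species"),
                            min_per_period = 2) {
  balance <- match.arg(balance)
  stopifnot(n_replicates >= 1)
  if (length(unique(records$group)) > 1)
    stop("records must be from a single taxon group; subset to bees or plants")
  if (is.null(taxa)) taxa <- filter_shared_species(records, min_per_period)
  if (length(taxa) == 0) stop("no taxa to estimate")
  if (!is.null(seed)) set.seed(seed)

  ind <- expand_individuals(records[records$taxon %in% taxa, , drop = FALSE])
  elev <- ind$elevation_m
  bins <- assign_bin(elev, scheme)
  period <- ifelse(ind$period == "modern", 2L, 1L)
  tax <- factor(ind$taxon, levels = taxa)
  ti <- as.integer(tax)
  S <- length(taxa)

  # per-bin, per-period index lists; species-mode nests them by taxon
  cells <- if (balance == "community")
    split(seq_along(elev), list(bin = bins, period = period), drop = TRUE)
  else
    split(seq_along(elev), list(bin = bins, period = period, taxon = ti),
          drop = TRUE)
  key <- do.call(rbind, strsplit(names(cells), ".", fixed = TRUE))
  pair_id <- if (balance == "community") key[, 1] else
    paste(key[, 1], key[, 3])
  per <- as.integer(key[, 2])
  pairs <- lapply(unique(pair_id), function(pid) {
    h <- cells[pair_id == pid & per == 1L]
    m <- cells[pair_id == pid & per == 2L]
    if (length(h) == 1 && length(m) == 1) list(h = h[[1]], m = m[[1]]) else NULL
  })
  pairs <- Filter(Negate(is.null), pairs)
  if (length(pairs) == 0)
    stop("no elevation bin is occupied in both periods")

  grp <- ti + S * (period - 1L)          # taxon x period cell index
  sum_d <- sum_d2 <- sum_mh <- sum_mm <- numeric(S)
  used <- integer(S)
  for (r in seq_len(n_replicates)) {
    keep <- unlist(lapply(pairs, function(pr) {
      k <- min(length(pr$h), length(pr$m))
      c(if (length(pr$h) == k) pr$h else pr$h[sample.int(length(pr$h), k)],
        if (length(pr$m) == k) pr$m else pr$m[sample.int(length(pr$m), k)])
    }), use.names = FALSE)
    cnt <- tabulate(grp[keep], nbins = 2L * S)
    sums <- numeric(2L * S)
    rs <- rowsum(elev[keep], grp[keep])
    sums[as.integer(rownames(rs))] <- rs[, 1]
    ok <- cnt[1:S] > 0 & cnt[(S + 1):(2 * S)] > 0
    mh <- sums[1:S][ok] / cnt[1:S][ok]
    mm <- sums[(S + 1):(2 * S)][ok] / cnt[(S + 1):(2 * S)][ok]
    d <- mm - mh
    sum_d[ok] <- sum_d[ok] + d
    sum_d2[ok] <- sum_d2[ok] + d^2
    sum_mh[ok] <- sum_mh[ok] + mh
    sum_mm[ok] <- sum_mm[ok] + mm
    used[ok] <- used[ok] + 1L
  }

  shift <- ifelse(used > 0, sum_d / used, NA_real_)
  rep_sd <- ifelse(used > 1,
                   sqrt(pmax(0, (sum_d2 - used * (sum_d / used)^2) / (used - 1))),
                   ifelse(used == 1, 0, NA_real_))
  obs_stat <- function(f, p) vapply(seq_len(S), function(s) {
    x <- elev[ti == s & period == p]
    if (length(x)) f(x) else NA_real_
  }, numeric(1))
  out <- data.frame(
    taxon = taxa,
    n_hist = tabulate(ti[period == 1L], S),
    n_mod = tabulate(ti[period == 2L], S),
    mean_hist = ifelse(used > 0, sum_mh / used, NA_real_),
    mean_mod = ifelse(used > 0, sum_mm / used, NA_real_),
    shift_m = shift,
    replicate_sd = rep_sd,
    n_replicates_used = used,
    n_replicates_skipped = n_replicates - used,
    min_hist = obs_stat(min, 1L), max_hist = obs_stat(max, 1L),
    min_mod = obs_stat(min, 2L), max_mod = obs_stat(max, 2L),
    stringsAsFactors = FALSE)
  if (any(used == 0))
    warning("undefined estimate (taxon never present in both periods of a ",
            "balanced replicate): ",
            paste(taxa[used == 0], collapse = ", "))
  attr(out, "n_replicates") <- as.integer(n_replicates)
  attr(out, "balance") <- balance
  class(out) <- c("shift_estimates", "data.frame")
  out
}

#' Community-level test of the overall shift
#'
#' Tests whether the community's per-species shifts differ from zero.
#' Normality of the shift values is assessed with a Shapiro--Wilk test; if
#' not rejected (p >= \code{alpha_normality}) a two-sided one-sample t-test
#' with \code{df = n - 1} and its 95\% CI of the mean are reported, otherwise
#' a one-sample Wilcoxon signed-rank test against zero with a
#' Hodges--Lehmann CI.
#'
#' @param estimates a \code{shift_estimates} data frame (or any data frame
#'   with a \code{shift_m} column); undefined estimates are dropped
#' @param alpha_normality Shapiro--Wilk gate (default 0.05)
#' @return list of class \code{community_shift_test}: \code{test_used},
#'   \code{statistic}, \code{df} (t only), \code{p_value}, \code{ci95},
#'   \code{mean_shift_m}, \code{estimate}, \code{n_species},
#'   \code{normality_p}, \code{p_floor} (TRUE when p underflowed)
#' @export
overall_shift_test <- function(estimates, alpha_normality = 0.05) {
  x <- estimates$shift_m
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("need at least 3 defined shift estimates, got ", n)
  if (stats::sd(x) == 0) {
    # degenerate community: all shifts identical; p underflows any floor
    res <- list(test_used = "t_one_sample",
                statistic = if (x[1] == 0) 0 else Inf,
                df = n - 1, p_value = if (x[1] == 0) 1 else 0,
                ci95 = c(x[1], x[1]), mean_shift_m = x[1], estimate = x[1],
                n_species = n, normality_p = NA_real_, p_floor = x[1] != 0)
    class(res) <- "community_shift_test"
    return(res)
  }
  sw <- stats::shapiro.test(x)
  if (sw$p.value >= alpha_normality) {
    tt <- stats::t.test(x, mu = 0)
    res <- list(test_used = "t_one_sample",
                statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, ci95 = unname(tt$conf.int),
                mean_shift_m = mean(x), estimate = mean(x))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, mu = 0, conf.int = TRUE))
    res <- list(test_used = "wilcoxon_signed_rank",
                statistic = unname(wt$statistic), df = NA_real_,
                p_value = wt$p.value, ci95 = unname(wt$conf.int),
                mean_shift_m = mean(x), estimate = unname(wt$estimate))
  }
  res$n_species <- n
  res$normality_p <- sw$p.value
  res$p_floor <- res$p_value < .Machine$double.xmin
  class(res) <- "community_shift_test"
  res
}

#' @export
print.community_shift_test <- function(x, ...) {
  lab <- if (x$test_used == "t_one_sample")
    sprintf("one-sample t: t = %.3g, df = %d", x$statistic, x$df)
  else
    sprintf("Wilcoxon signed-rank: V = %.4g", x$statistic)
  cat(sprintf("Overall shift test (n = %d species)\n  %s, p = %.3g%s\n",
              x$n_species, lab, x$p_value,
              if (isTRUE(x$p_floor)) " (below floating-point floor)" else ""))
  cat(sprintf("  mean shift = %.1f m, 95%% CI [%.1f, %.1f] m\n",
              x$mean_shift_m, x$ci95[1], x$ci95[2]))
  cat(sprintf("  Shapiro-Wilk normality p = %.3g\n", x$normality_p))
  invisible(x)
}
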