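# Size-based rarefaction and extrapolation of species richness (Hill
# number 0), implemented from the standard combinatorial and Chao1 formulas
# with log-scale binomial coefficients, plus a multinomial bootstrap for
# confidence bands.

#' Build an abundance vector
#'
#' @param counts named vector of positive integer counts (taxon -> count),
#'   or an unnamed vector (taxa are then auto-labelled)
#' @return object of class \code{abundance_vector}: list with \code{counts},
#'   \code{n} (total individuals), \code{s_obs} (observed richness),
#'   \code{f1}, \code{f2} (singleton/doubleton counts)
#' @export
abundance_vector <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("empty abundance vector")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (is.null(names(counts))) names(counts) <- paste0("sp", seq_along(counts))
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 n = as.integer(sum(counts)),
                 s_obs = length(counts), f1 = sum(counts == 1),
                 f2 = sum(counts == 2)),
            class = "abundance_vector")
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat(sprintf("Abundance vector: S_obs = %d, n = %d, f1 = %d, f2 = %d\n",
              x$s_obs, x$n, x$f1, x$f2))
  invisible(x)
}

#' Interpolated (rarefied) species richness
#'
#' Expected number of species in a uniform random subsample of \code{m}
#' individuals: \deqn{S(m) = S_{obs} - \sum_i \binom{n - x_i}{m} /
#' \binom{n}{m}.} Binomial coefficients are evaluated on the log scale so
#' large samples do not overflow. \code{S(1) = 1} and \code{S(n) = S_obs}
#' identically.
#'
#' @param abund an [abundance_vector()]
#' @param m sample size(s), integers in \code{1..n}
#' @return expected richness, one value per element of \code{m}
#' @export
interpolate_richness <- function(abund, m) {
  stopifnot(inherits(abund, "abundance_vector"))
  if (any(m < 1 | m > abund$n | m != round(m)))
    stop("m must be integers in 1..n = ", abund$n)
  x <- abund$counts
  n <- abund$n
  vapply(m, function(mm) {
    term <- ifelse(n - x >= mm, exp(lchoose(n - x, mm) - lchoose(n, mm)), 0)
    abund$s_obs - sum(term)
  }, numeric(1))
}

# Chao1 estimate of the number of unseen species
chao_f0 <- function(abund) {
  n <- abund$n
  if (abund$f1 == 0) return(0)
  if (abund$f2 > 0)
    (n - 1) / n * abund$f1^2 / (2 * abund$f2)
  else
    (n - 1) / n * abund$f1 * (abund$f1 - 1) / 2
}

#' Extrapolated species richness
#'
#' Expected richness after sampling \code{m_star} additional individuals
#' beyond the observed \code{n}, from the Chao1 asymptotic estimator:
#' \deqn{S(n + m^*) = S_{obs} + \hat f_0 [1 - (1 - f_1 / (n \hat f_0 +
#' f_1))^{m^*}]} with \eqn{\hat f_0 = \frac{n-1}{n} f_1^2 / (2 f_2)} when
#' doubletons exist, else \eqn{\frac{n-1}{n} f_1 (f_1 - 1) / 2}. Approaches
#' \eqn{S_{obs} + \hat f_0} monotonically from below; with no singletons the
#' curve is flat at \code{S_obs} (flagged with a warning).
#'
#' @param abund an [abundance_vector()]
#' @param m_star additional individuals beyond \code{n} (>= 0); values
#'   beyond \code{n} (i.e. extrapolation past twice the sample) draw a
#'   warning, reflecting standard guidance
#' @return expected richness, one value per element of \code{m_star}
#' @export
extrapolate_richness <- function(abund, m_star) {
  stopifnot(inherits(abund, "abundance_vector"))
  if (any(m_star < 0)) stop("m_star must be >= 0")
  if (any(m_star > abund$n))
    warning("extrapolating beyond twice the observed sample size; ",
            "estimates are increasingly model-dependent")
  f0 <- chao_f0(abund)
  if (abund$f1 == 0 && any(m_star > 0))
    warning("no singletons: extrapolated curve is flat at S_obs")
  if (f0 == 0) return(rep(abund$s_obs, length(m_star)))
  abund$s_obs +
    f0 * (1 - (1 - abund$f1 / (abund$n * f0 + abund$f1))^m_star)
}

#' Rarefaction/extrapolation curve with bootstrap confidence bands
#'
#' Point estimates come from [interpolate_richness()] for \code{m <= n} and
#' [extrapolate_richness()] beyond; at \code{m = n} the two meet at
#' \code{S_obs}. Confidence bands use the standard multinomial bootstrap
#' over the Chao-adjusted community: seen species get probabilities
#' \eqn{\hat C x_i / n} (with \eqn{\hat C} the sample-coverage estimate) and
#' the \eqn{\lceil \hat f_0 \rceil} estimated unseen species share the
#' remaining mass equally; \code{n_boot} resamples of size \code{n} are
#' drawn, curves recomputed, and bands set at \eqn{\pm 1.96} bootstrap SD.
#'
#' @param abund an [abundance_vector()]
#' @param m_grid sample sizes; default ~40 knots from 1 to \code{2n}
#' @param n_boot bootstrap replicates (default 200)
#' @param seed optional integer seed
#' @param conf confidence level (default 0.95)
#' @return data frame of class \code{rarefaction_curve}: \code{m, method}
#'   (interpolated/observed/extrapolated), \code{richness, se, ci_lo, ci_hi}
#' @export
rarefaction_curve <- function(abund, m_grid = NULL, n_boot = 200, seed = NULL,
                              conf = 0.95) {
  stopifnot(inherits(abund, "abundance_vector"), n_boot >= 2)
  n <- abund$n
  if (is.null(m_grid))
    m_grid <- unique(sort(c(1, round(seq(1, 2 * n, length.out = 40)), n)))
  stopifnot(all(m_grid >= 1), all(m_grid == round(m_grid)))
  point <- function(ab, grid) {
    lo <- grid[grid <= ab$n]
    hi <- grid[grid > ab$n]
    c(if (length(lo)) interpolate_richness(ab, lo),
      if (length(hi)) suppressWarnings(extrapolate_richness(ab, hi - ab$n)))
  }
  est <- point(abund, m_grid)

  # Chao-adjusted bootstrap community
  f0 <- ceiling(chao_f0(abund))
  cover <- if (abund$f1 == 0) 1 else {
    1 - abund$f1 / n * ((n - 1) * abund$f1 /
                          ((n - 1) * abund$f1 + 2 * abund$f2))
  }
  p <- c(cover * abund$counts / n,
         if (f0 > 0) rep((1 - cover) / f0, f0))
  p <- p / sum(p)
  if (!is.null(seed)) set.seed(seed)
  boot <- matrix(NA_real_, n_boot, length(m_grid))
  for (b in seq_len(n_boot)) {
    cnt <- stats::rmultinom(1, n, p)[, 1]
    boot[b, ] <- point(abundance_vector(cnt), m_grid)
  }
  se <- apply(boot, 2, stats::sd)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- data.frame(m = m_grid,
                    method = ifelse(m_grid < n, "interpolated",
                                    ifelse(m_grid == n, "observed",
                                           "extrapolated")),
                    richness = est, se = se,
                    ci_lo = pmax(est - z * se, 1), ci_hi = est + z * se,
                    stringsAsFactors = FALSE)
  attr(out, "s_obs") <- abund$s_obs
  attr(out, "n") <- n
  attr(out, "n_boot") <- n_boot
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

#' Assemble abundance vectors by elevation stratum
#'
#' Counts individuals per taxon within disjoint elevation strata (and one
#' period), the inputs to stratified richness comparisons at equal sample
#' size.
#'
#' @param records occurrence data frame
#' @param strata list of length-2 vectors \code{c(lo_m, hi_m)}; must be
#'   disjoint. Half-open \code{[lo, hi)} except the last, closed at its top.
#' @param period \code{"historical"}, \code{"modern"} or \code{NULL} (both
#'   pooled)
#' @return named list (one element per stratum, \code{"lo-hi"}) of
#'   [abundance_vector()]s; empty strata yield \code{NULL} with a warning
#' @export
richness_by_stratum <- function(records, strata, period = NULL) {
  los <- vapply(strata, `[`, numeric(1), 1)
  his <- vapply(strata, `[`, numeric(1), 2)
  ord <- order(los)
  if (any(los[ord][-1] < his[ord][-length(his)]))
    stop("strata must be disjoint")
  if (!is.null(period)) records <- records[records$period == period, ,
                                           drop = FALSE]
  ind <- expand_individuals(records)
  out <- stats::setNames(vector("list", length(strata)),
                         sprintf("%g-%g", los, his))
  for (s in seq_along(strata)) {
    closed_top <- los[s] == max(los)
    sel <- ind$elevation_m >= los[s] &
      (if (closed_top) ind$elevation_m <= his[s] else ind$elevation_m < his[s])
    if (!any(sel)) {
      warning(sprintf("stratum [%g, %g] is empty", los[s], his[s]))
      next
    }
    out[[s]] <- abundance_vector(table(ind$taxon[sel]))
  }
  out
}
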