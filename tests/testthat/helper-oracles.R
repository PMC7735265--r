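# Shared fixtures and independent oracles, all built in code.

# quick occurrence data frame
make_records <- function(taxon, period, elevation_m, group = "bee",
                         visited_plant = NA_character_, n_individuals = 1L,
                         site = NA_character_) {
  k <- max(length(taxon), length(period), length(elevation_m),
           length(visited_plant), length(n_individuals), length(site))
  data.frame(record_id = sprintf("t%04d", seq_len(k)),
             taxon = rep_len(taxon, k), group = rep_len(group, k),
             period = rep_len(period, k),
             elevation_m = rep_len(elevation_m, k),
             visited_plant = rep_len(visited_plant, k),
             site = rep_len(site, k),
             n_individuals = rep_len(as.integer(n_individuals), k),
             stringsAsFactors = FALSE)
}

# exhaustive-enumeration oracle for rarefied richness: mean distinct-species
# count over all C(n, m) subsets of individuals
brute_richness <- function(counts, m) {
  sp <- rep(seq_along(counts), counts)
  subsets <- utils::combn(length(sp), m)
  mean(apply(subsets, 2, function(ix) length(unique(sp[ix]))))
}

# all integer partitions of n (multisets of positive counts summing to n)
partitions_of <- function(n, max_part = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (k in seq(min(n, max_part), 1)) {
    for (rest in partitions_of(n - k, k))
      out[[length(out) + 1L]] <- c(k, rest)
  }
  out
}

# exhaustive-enumeration oracle for the balanced-resampling estimator:
# expected per-taxon (modern - historical) mean-elevation difference over
# ALL equally likely balanced subsets (community-level balancing). Feasible
# when every bin's larger period is small.
enum_balanced_expectation <- function(records, scheme, taxa) {
  ind <- records[rep(seq_len(nrow(records)), records$n_individuals), ]
  bins <- assign_bin(ind$elevation_m, scheme)
  per_bin <- list()
  for (b in sort(unique(bins))) {
    h <- which(bins == b & ind$period == "historical")
    m <- which(bins == b & ind$period == "modern")
    if (length(h) == 0 || length(m) == 0) next
    k <- min(length(h), length(m))
    hs <- utils::combn(length(h), k)
    ms <- utils::combn(length(m), k)
    choices <- list()
    for (i in seq_len(ncol(hs))) for (j in seq_len(ncol(ms)))
      choices[[length(choices) + 1L]] <- c(h[hs[, i]], m[ms[, j]])
    per_bin[[length(per_bin) + 1L]] <- choices
  }
  grid <- do.call(expand.grid, lapply(per_bin, seq_along))
  sums <- stats::setNames(numeric(length(taxa)), taxa)
  cnts <- stats::setNames(numeric(length(taxa)), taxa)
  for (r in seq_len(nrow(grid))) {
    keep <- unlist(lapply(seq_along(per_bin),
                          function(p) per_bin[[p]][[grid[r, p]]]))
    sub <- ind[keep, ]
    for (tx in taxa) {
      eh <- sub$elevation_m[sub$taxon == tx & sub$period == "historical"]
      em <- sub$elevation_m[sub$taxon == tx & sub$period == "modern"]
      if (length(eh) && length(em)) {
        sums[tx] <- sums[tx] + mean(em) - mean(eh)
        cnts[tx] <- cnts[tx] + 1
      }
    }
  }
  sums / cnts
}

# criterion-3 style recovery scenario: 12 species stacked along the
# gradient, equal survey protocol in both periods
recovery_scenario <- function(seed, n_species = 12, n_per_period = 300,
                              niche_sd = 100, shift_range = c(-100, 300)) {
  set.seed(seed)
  shifts <- stats::runif(n_species, shift_range[1], shift_range[2])
  sp <- data.frame(name = sprintf("b%02d", seq_len(n_species)), group = "bee",
                   true_mean_hist_m = seq(1500, 2400,
                                          length.out = n_species),
                   true_shift_m = shifts, niche_sd_m = niche_sd,
                   abundance_weight = n_per_period, stringsAsFactors = FALSE)
  resurvey_scenario(sp, bin_scheme(1000, 3000, 200), seed = seed * 997L)
}

# per-species standard error of the raw difference of period means
raw_diff_se <- function(occ, taxa) {
  vapply(taxa, function(tx) {
    x <- occ[occ$taxon == tx, ]
    eh <- x$elevation_m[x$period == "historical"]
    em <- x$elevation_m[x$period == "modern"]
    sqrt(stats::var(eh) / length(eh) + stats::var(em) / length(em))
  }, numeric(1))
}
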