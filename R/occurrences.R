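# Occurrence tables: delimited-text reading/writing, validation, taxonomic
# harmonization and the shared-species filter applied before shift estimation.

OCC_REQUIRED <- c("taxon", "group", "period", "elevation_m")
OCC_COLUMNS  <- c("record_id", "taxon", "group", "period", "elevation_m",
                  "visited_plant", "site", "n_individuals")

#' Read an occurrence table
#'
#' Reads a delimited text table of dated observations: one row per record of a
#' taxon (bee or plant) at an elevation in one survey period, optionally
#' carrying the plant a bee was caught visiting. Required columns:
#' \code{taxon}, \code{group} (\code{bee}/\code{plant}), \code{period}
#' (\code{historical}/\code{modern}), \code{elevation_m}. Optional:
#' \code{record_id}, \code{visited_plant}, \code{site}, \code{n_individuals}
#' (positive integer, default 1).
#'
#' Rows whose elevation does not parse as a number, or falls outside
#' \code{bounds}, raise an error naming the offending rows — they are never
#' silently dropped.
#'
#' @param path path to a delimited text file with a header row
#' @param delim field delimiter (default comma)
#' @param bounds permissible elevation range in metres (default 900--3000,
#'   the survey envelope)
#' @return a validated occurrence data frame (see [validate_occurrences()])
#' @export
read_occurrences <- function(path, delim = ",", bounds = c(900, 3000)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          colClasses = "character", stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "", fileEncoding = "UTF-8")
  if (nrow(df) == 0) stop("empty occurrence table: ", path)
  missing_cols <- setdiff(OCC_REQUIRED, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  elev <- suppressWarnings(as.numeric(df$elevation_m))
  bad <- which(is.na(elev))
  if (length(bad))
    stop("unparseable elevation_m in row(s): ", paste(bad, collapse = ", "))
  df$elevation_m <- elev
  if (!"n_individuals" %in% names(df) || all(df$n_individuals == "")) {
    df$n_individuals <- 1L
  } else {
    n <- suppressWarnings(as.integer(df$n_individuals))
    n[is.na(n) & (is.na(df$n_individuals) | df$n_individuals == "")] <- 1L
    if (anyNA(n) || any(n < 1))
      stop("n_individuals must be positive integers (row(s): ",
           paste(which(is.na(n) | n < 1), collapse = ", "), ")")
    df$n_individuals <- n
  }
  for (col in c("record_id", "visited_plant", "site"))
    if (!col %in% names(df)) df[[col]] <- NA_character_
  df$visited_plant[!is.na(df$visited_plant) & df$visited_plant == ""] <- NA_character_
  df$site[!is.na(df$site) & df$site == ""] <- NA_character_
  if (all(is.na(df$record_id)) || all(df$record_id == ""))
    df$record_id <- sprintf("r%05d", seq_len(nrow(df)))
  df <- df[OCC_COLUMNS]
  validate_occurrences(df, bounds = bounds)
}

#' Validate an occurrence data frame
#'
#' Checks the invariants of the occurrence schema: known group and period
#' levels, elevations within the survey bounds, positive integer counts, and
#' no \code{visited_plant} on plant records (cleared with a warning).
#'
#' @param records occurrence data frame
#' @param bounds permissible elevation range (metres)
#' @return the records, invisibly corrected where the schema allows it
#' @export
validate_occurrences <- function(records, bounds = c(900, 3000)) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(OCC_REQUIRED, names(records))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  bad_group <- !records$group %in% c("bee", "plant")
  if (any(bad_group))
    stop("unknown group in row(s): ", paste(which(bad_group), collapse = ", "),
         " (expected 'bee' or 'plant')")
  bad_period <- !records$period %in% c("historical", "modern")
  if (any(bad_period))
    stop("unknown period in row(s): ", paste(which(bad_period), collapse = ", "),
         " (expected 'historical' or 'modern')")
  out <- records$elevation_m < bounds[1] | records$elevation_m > bounds[2]
  if (any(out))
    stop(sprintf("elevation_m outside survey bounds [%g, %g] in row(s): %s",
                 bounds[1], bounds[2],
                 paste(utils::head(which(out), 10), collapse = ", ")))
  if (!"n_individuals" %in% names(records)) records$n_individuals <- 1L
  if (any(records$n_individuals < 1) ||
      any(records$n_individuals != round(records$n_individuals)))
    stop("n_individuals must be positive integers")
  if ("visited_plant" %in% names(records)) {
    offending <- records$group == "plant" & !is.na(records$visited_plant)
    if (any(offending)) {
      warning(sum(offending), " plant record(s) carried visited_plant; cleared")
      records$visited_plant[offending] <- NA_character_
    }
  }
  records
}

#' Write an occurrence table
#'
#' Writes the standard delimited occurrence format; a round trip through
#' [read_occurrences()] reproduces every field.
#'
#' @param records occurrence data frame
#' @param path output file path
#' @param delim field delimiter
#' @export
write_occurrences <- function(records, path, delim = ",") {
  cols <- intersect(OCC_COLUMNS, names(records))
  utils::write.table(records[cols], path, sep = delim, row.names = FALSE,
                     quote = TRUE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a synonym (name-harmonization) table
#'
#' Columns: \code{historical_name}, \code{accepted_name}, \code{group}. The
#' mapping must be functional — each historical name maps to exactly one
#' accepted name — though several historical names may share one accepted
#' name (a merge, e.g. two species pooled into one species group).
#'
#' @param path delimited text file
#' @param delim field delimiter
#' @return data frame of class \code{synonym_table}
#' @export
read_synonyms <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          colClasses = "character", stringsAsFactors = FALSE,
                          quote = "\"", fileEncoding = "UTF-8")
  synonym_table(df)
}

#' Construct a synonym table from a data frame
#' @param df data frame with columns historical_name, accepted_name, group
#' @return the data frame, classed \code{synonym_table}
#' @export
synonym_table <- function(df) {
  need <- c("historical_name", "accepted_name", "group")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  dup <- duplicated(df$historical_name)
  if (any(dup))
    stop("synonym mapping is not functional; duplicated historical name(s): ",
         paste(unique(df$historical_name[dup]), collapse = ", "))
  class(df) <- c("synonym_table", "data.frame")
  df
}

#' Harmonize taxon names against a synonym table
#'
#' Replaces each historical name by its accepted name, per taxon group.
#' Unmapped names pass through unchanged and are tallied in the attached
#' report; merges (several historical names onto one accepted name) are
#' logged there too. A table entry whose group tag conflicts with a record's
#' group triggers a warning and no rename. Bee records' \code{visited_plant}
#' names are harmonized against the table's plant entries.
#'
#' Applying the same table twice equals applying it once, provided accepted
#' names do not themselves appear as historical names (chained mappings draw
#' a warning).
#'
#' @param records occurrence data frame
#' @param table a [synonym_table()] (or data frame with its columns)
#' @return records with renamed taxa; attribute \code{"harmonization"} holds a
#'   list with \code{unmapped} (name -> record count), \code{merged}
#'   (accepted names that received > 1 historical name) and \code{renamed}
#'   (number of renames applied)
#' @export
harmonize <- function(records, table) {
  if (!inherits(table, "synonym_table")) table <- synonym_table(table)
  if (nrow(table)) {
    chained <- intersect(table$accepted_name, table$historical_name)
    chained <- setdiff(chained, table$historical_name[
      table$historical_name == table$accepted_name])
    if (length(chained))
      warning("accepted name(s) also appear as historical names (chained ",
              "mapping, harmonize will not be idempotent): ",
              paste(chained, collapse = ", "))
  }
  renamed <- 0L
  for (grp in unique(records$group)) {
    sub <- table[table$group == grp, , drop = FALSE]
    idx <- which(records$group == grp)
    m <- match(records$taxon[idx], sub$historical_name)
    hit <- !is.na(m) & sub$accepted_name[m] != records$taxon[idx]
    records$taxon[idx][hit] <- sub$accepted_name[m][hit]
    renamed <- renamed + sum(hit)
    # same name registered under the other group: warn, leave unchanged
    other <- table[table$group != grp, , drop = FALSE]
    conflict <- is.na(m) & records$taxon[idx] %in% other$historical_name
    if (any(conflict))
      warning("group tag conflict, not renamed: ",
              paste(unique(records$taxon[idx][conflict]), collapse = ", "))
  }
  if ("visited_plant" %in% names(records)) {
    plants <- table[table$group == "plant", , drop = FALSE]
    m <- match(records$visited_plant, plants$historical_name)
    hit <- !is.na(m)
    records$visited_plant[hit] <- plants$accepted_name[m][hit]
  }
  unmapped_names <- setdiff(unique(records$taxon),
                            c(table$accepted_name, table$historical_name))
  unmapped <- table(factor(records$taxon, levels = unmapped_names))
  merged <- names(which(table(table$accepted_name) > 1))
  attr(records, "harmonization") <- list(
    unmapped = as.list(unmapped), merged = merged, renamed = renamed)
  records
}

#' Taxa observed in both periods
#'
#' Returns the taxa with at least \code{min_per_period} individuals (summing
#' \code{n_individuals}) in \emph{each} of the two periods — the inclusion
#' rule for shift estimation ("observed at least twice in both periods").
#'
#' @param records occurrence data frame (subset to one taxon group first if
#'   bees and plants are to be filtered separately)
#' @param min_per_period minimum individuals per period (default 2)
#' @return sorted character vector of qualifying taxa
#' @export
filter_shared_species <- function(records, min_per_period = 2) {
  stopifnot(is.data.frame(records), min_per_period >= 1)
  n <- if ("n_individuals" %in% names(records)) records$n_individuals else
    rep(1L, nrow(records))
  tab <- tapply(n, list(records$taxon, records$period), sum, default = 0L)
  for (p in c("historical", "modern"))
    if (!p %in% colnames(tab))
      tab <- cbind(tab, matrix(0L, nrow(tab), 1, dimnames = list(NULL, p)))
  keep <- tab[, "historical"] >= min_per_period & tab[, "modern"] >= min_per_period
  sort(rownames(tab)[keep])
}
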