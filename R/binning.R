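#' Elevation binning scheme
#'
#' Defines half-open 200 m elevation classes used to stratify the balanced
#' resampling of occurrence records, e.g. 1000--1200, 1200--1400, ...,
#' 2000--2200 m. Every bin is half-open \code{[b, b + width)} except the
#' topmost, which is closed at \code{upper_m} so the full survey range is
#' partitioned.
#'
#' @param lower_m lower edge of the first bin (metres a.s.l.)
#' @param upper_m upper edge of the last bin; \code{upper_m - lower_m} must be
#'   divisible by \code{width_m}
#' @param width_m bin width in metres (default 200)
#' @return an object of class \code{bin_scheme} with elements \code{lower_m},
#'   \code{upper_m}, \code{width_m}, \code{breaks} and \code{n_bins}
#' @examples
#' sch <- bin_scheme(1000, 2200)
#' assign_bin(c(1000, 1199, 1200, 2200), sch)
#' @seealso [assign_bin()]
#' @export
bin_scheme <- function(lower_m, upper_m, width_m = 200) {
  stopifnot(is.numeric(lower_m), is.numeric(upper_m), is.numeric(width_m),
            length(lower_m) == 1, length(upper_m) == 1, length(width_m) == 1,
            width_m > 0)
  if (upper_m <= lower_m)
    stop("upper_m must exceed lower_m")
  span <- upper_m - lower_m
  if (abs(span / width_m - round(span / width_m)) > 1e-9)
    stop("(upper_m - lower_m) must be divisible by width_m")
  n_bins <- as.integer(round(span / width_m))
  structure(
    list(lower_m = lower_m, upper_m = upper_m, width_m = width_m,
         breaks = seq(lower_m, upper_m, by = width_m), n_bins = n_bins),
    class = "bin_scheme")
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("Elevation binning: %d bins of %g m over [%g, %g] m\n",
              x$n_bins, x$width_m, x$lower_m, x$upper_m))
  invisible(x)
}

#' Assign elevations to bins
#'
#' Maps each elevation to the 1-based index of the half-open bin
#' \code{[b, b + width)} containing it; the scheme's upper bound maps into the
#' last bin (closed top), so the bins partition \code{[lower_m, upper_m]}.
#'
#' @param elevation_m numeric vector of elevations (metres)
#' @param scheme a [bin_scheme()]
#' @return integer vector of bin indices in \code{1:scheme$n_bins}
#' @export
assign_bin <- function(elevation_m, scheme) {
  stopifnot(inherits(scheme, "bin_scheme"), is.numeric(elevation_m))
  out_of_range <- elevation_m < scheme$lower_m | elevation_m > scheme$upper_m
  if (any(out_of_range, na.rm = TRUE) || anyNA(elevation_m))
    stop(sprintf("elevations outside [%g, %g]: %s",
                 scheme$lower_m, scheme$upper_m,
                 paste(utils::head(elevation_m[out_of_range | is.na(elevation_m)], 5),
                       collapse = ", ")))
  findInterval(elevation_m, scheme$breaks, rightmost.closed = TRUE)
}

#' Bin edges as a data frame
#'
#' @param scheme a [bin_scheme()]
#' @return data frame with columns \code{bin}, \code{lo_m}, \code{hi_m}
#' @export
bin_edges <- function(scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  data.frame(bin = seq_len(scheme$n_bins),
             lo_m = scheme$breaks[-length(scheme$breaks)],
             hi_m = scheme$breaks[-1])
}
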