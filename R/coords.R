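#' Coordinate conventions
#'
#' All intervals inside the package are 0-based half-open `[start, end)`.
#' External text formats differ: GFF3, VCF and the region/marker TSVs are
#' 1-based inclusive, BED is 0-based half-open. Conversion happens only at
#' the I/O boundary, and only through the two functions below, so that the
#' convention is audited in exactly one place.
#'
#' A zero-length internal interval `[p, p)` (an anchored insertion point)
#' maps to the 1-based inclusive pair `(p + 1, p)` -- start one greater
#' than end -- which round-trips losslessly.
#'
#' @param start,end integer vectors; for `coords_to_1based` these are
#'   internal 0-based half-open coordinates, for `coords_from_1based`
#'   1-based inclusive coordinates.
#' @return a list with integer components `start` and `end` in the target
#'   convention.
#' @examples
#' coords_to_1based(0L, 1L)    # first base -> (1, 1)
#' coords_from_1based(5L, 5L)  # length-1 interval -> [4, 5)
#' @export
coords_to_1based <- function(start, end) {
  stopifnot(all(end >= start, na.rm = TRUE))
  list(start = as.integer(start) + 1L, end = as.integer(end))
}

#' @rdname coords_to_1based
#' @export
coords_from_1based <- function(start, end) {
  stopifnot(all(end >= start - 1L, na.rm = TRUE))
  list(start = as.integer(start) - 1L, end = as.integer(end))
}
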