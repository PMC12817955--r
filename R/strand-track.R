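#' Dense per-position read-start / coverage track for one strand
#'
#' A `strand_track` holds one non-negative integer count per genome position
#' for a single strand of a single library replicate. Tracks are the carrier
#' for bedgraph content: parsing and writing happen in [read_bedgraph()] and
#' [write_bedgraph()], everything downstream works on the dense vector.
#'
#' Internal coordinates throughout the package are 0-based, half-open and
#' strand-explicit; position `i` of the genome is element `i + 1` of
#' `counts`.
#'
#' @param counts Non-negative numeric vector, one value per genome position.
#' @param strand `"+"` or `"-"`.
#' @param library Free-text library label (e.g. `"plus_tex"`, `"coip"`).
#' @param replicate Integer replicate index.
#'
#' @return An object of class `strand_track`: a list with elements `counts`,
#'   `strand`, `library`, `replicate` and `library_size` (the total count).
#' @export
#' @examples
#' tr <- strand_track(c(0, 5, 5, 0, 2), strand = "+")
#' tr$library_size
strand_track <- function(counts, strand = "+", library = "lib",
                         replicate = 1L) {
  counts <- as.numeric(counts)
  if (length(counts) < 1L) stop("`counts` must have length >= 1")
  if (anyNA(counts) || any(counts < 0)) {
    stop("track counts must be non-negative and non-missing")
  }
  check_strand(strand)
  structure(
    list(
      counts = counts,
      strand = strand,
      library = as.character(library),
      replicate = as.integer(replicate),
      library_size = sum(counts)
    ),
    class = "strand_track"
  )
}

#' @export
print.strand_track <- function(x, ...) {
  cat(sprintf(
    "<strand_track> %s strand, library '%s' rep %d: %d positions, %s total counts\n",
    x$strand, x$library, x$replicate, length(x$counts),
    format(x$library_size, big.mark = ",")
  ))
  invisible(x)
}

#' @export
length.strand_track <- function(x) length(x$counts)

# strand symbols are validated in exactly one place
check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-' (got: ",
         paste(unique(setdiff(strand, c("+", "-"))), collapse = ", "), ")")
  }
  invisible(strand)
}

# Sum counts over a list of replicate tracks (or pass one track through).
# Used by the site caller, which tests summed replicate counts.
sum_tracks <- function(tracks) {
  if (inherits(tracks, "strand_track")) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1)
  n <- length(tracks[[1]]$counts)
  for (tr in tracks) {
    if (!inherits(tr, "strand_track")) stop("expected strand_track objects")
    if (length(tr$counts) != n) stop("replicate tracks differ in length")
  }
  out <- Reduce(`+`, lapply(tracks, `[[`, "counts"))
  strand_track(out, strand = tracks[[1]]$strand,
               library = tracks[[1]]$library, replicate = 0L)
}
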