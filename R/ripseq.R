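#' Coordinate-wise log2 fold change of coIP over mock coverage
#'
#' Each replicate track is scaled to the mean library size of all supplied
#' replicates, replicates are averaged within each arm, and the
#' per-position log2 ratio `log2((coip + pc) / (mock + pc))` is returned.
#' The pseudocount keeps zero-coverage positions finite (and exactly 0 when
#' both arms are empty).
#'
#' @param coip,mock A [strand_track()] or list of replicate tracks per arm.
#' @param pseudocount Added to both normalized means before the ratio.
#' @return A list with `log2fc` (numeric vector, one value per position),
#'   `coip_mean`, `mock_mean` (normalized averaged coverage) and `strand`.
#' @export
log2fc_track <- function(coip, mock, pseudocount = 1) {
  if (inherits(coip, "strand_track")) coip <- list(coip)
  if (inherits(mock, "strand_track")) mock <- list(mock)
  all_tracks <- c(coip, mock)
  sizes <- vapply(all_tracks, `[[`, numeric(1), "library_size")
  if (any(sizes == 0)) stop("zero library size in coIP/mock tracks")
  target <- mean(sizes)
  norm_mean <- function(tracks) {
    scaled <- lapply(tracks, function(tr) tr$counts * target / tr$library_size)
    Reduce(`+`, scaled) / length(scaled)
  }
  cm <- norm_mean(coip)
  mm <- norm_mean(mock)
  list(
    log2fc = log2((cm + pseudocount) / (mm + pseudocount)),
    coip_mean = cm, mock_mean = mm,
    strand = coip[[1]]$strand
  )
}

#' Find candidate interaction sites as runs of elevated log2 fold change
#'
#' Maximal runs of consecutive positions with `log2fc >= threshold` are
#' reported; runs shorter than `min_run` nt are discarded. Runs separated
#' by at least one below-threshold position stay distinct.
#'
#' @param log2fc Numeric vector of per-position log2 fold changes (or the
#'   list returned by [log2fc_track()]).
#' @param min_run Minimum run length in nt.
#' @param threshold Minimum per-position log2 fold change.
#' @return Tibble with `start`, `end` (0-based half-open).
#' @export
find_peaks <- function(log2fc, min_run = 10, threshold = 1) {
  if (is.list(log2fc)) log2fc <- log2fc$log2fc
  if (anyNA(log2fc) || any(!is.finite(log2fc))) {
    stop("log2fc array must be finite")
  }
  above <- log2fc >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_run
  tibble::tibble(start = as.integer(starts[keep]),
                 end = as.integer(ends[keep]))
}

#' Test candidate peaks for significant coIP enrichment
#'
#' A stand-in for a count-model DE test on per-peak counts: replicate read
#' sums within each peak are library-size normalized, log2 transformed
#' (pseudocount 1) and compared between arms with a Welch two-sample test;
#' p-values are Benjamini-Hochberg adjusted across all peaks of the
#' experiment. A peak is emitted when `padj < max_padj` and its mean
#' per-position log2 fold change is at least `min_lfc`. Externally computed
#' DESeq2-style tables can be substituted by the caller if preferred.
#'
#' @param peaks Tibble with `start`, `end` from [find_peaks()].
#' @param coip,mock Lists of replicate [strand_track()]s (>= 2 per arm for a
#'   p-value; with fewer, p is `NA` and the peak flagged untestable).
#' @param pseudocount Pseudocount used for the mean log2 fold change.
#' @param min_lfc,max_padj Emission thresholds.
#' @param keep_all Return all tested peaks instead of only emitted ones.
#' @return Tibble with `start`, `end`, `strand`, `width`, `mean_log2fc`,
#'   `pvalue`, `padj`.
#' @export
test_peaks <- function(peaks, coip, mock, pseudocount = 1, min_lfc = 1,
                       max_padj = 0.01, keep_all = FALSE) {
  if (inherits(coip, "strand_track")) coip <- list(coip)
  if (inherits(mock, "strand_track")) mock <- list(mock)
  if (nrow(peaks) > 0 && any(peaks$end <= peaks$start)) {
    stop("zero-width peak")
  }
  lfc <- log2fc_track(coip, mock, pseudocount = pseudocount)
  sizes <- vapply(c(coip, mock), `[[`, numeric(1), "library_size")
  target <- mean(sizes)
  peak_sums <- function(tracks) {
    vapply(tracks, function(tr) {
      f <- target / tr$library_size
      vapply(seq_len(nrow(peaks)), function(i) {
        sum(tr$counts[(peaks$start[i] + 1L):peaks$end[i]]) * f
      }, numeric(1))
    }, numeric(nrow(peaks)))
  }
  if (nrow(peaks) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character(), width = integer(),
                          mean_log2fc = numeric(), pvalue = numeric(),
                          padj = numeric()))
  }
  cs <- matrix(peak_sums(coip), nrow = nrow(peaks))
  ms <- matrix(peak_sums(mock), nrow = nrow(peaks))
  testable <- length(coip) >= 2 && length(mock) >= 2
  pvals <- vapply(seq_len(nrow(peaks)), function(i) {
    if (!testable) return(NA_real_)
    a <- log2(cs[i, ] + 1)
    b <- log2(ms[i, ] + 1)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    }
    stats::t.test(a, b, alternative = "greater")$p.value
  }, numeric(1))
  out <- tibble::tibble(
    start = peaks$start, end = peaks$end,
    strand = lfc$strand,
    width = peaks$end - peaks$start,
    mean_log2fc = vapply(seq_len(nrow(peaks)), function(i) {
      mean(lfc$log2fc[(peaks$start[i] + 1L):peaks$end[i]])
    }, numeric(1)),
    pvalue = pvals,
    padj = stats::p.adjust(pvals, method = "BH")
  )
  if (keep_all) return(out)
  dplyr::filter(out, !is.na(.data$padj), .data$padj < max_padj,
                .data$mean_log2fc >= min_lfc)
}

#' One-call RIP-seq peak calling on a strand
#'
#' Convenience wrapper: [log2fc_track()] then [find_peaks()] then
#' [test_peaks()].
#'
#' @inheritParams test_peaks
#' @param min_run,threshold Run definition, see [find_peaks()].
#' @return Emitted peak tibble, see [test_peaks()].
#' @export
call_peaks <- function(coip, mock, min_run = 10, threshold = 1,
                       pseudocount = 1, min_lfc = 1, max_padj = 0.01) {
  lfc <- log2fc_track(coip, mock, pseudocount = pseudocount)
  peaks <- find_peaks(lfc$log2fc, min_run = min_run, threshold = threshold)
  test_peaks(peaks, coip, mock, pseudocount = pseudocount,
             min_lfc = min_lfc, max_padj = max_padj)
}

#' Assign peaks to overlapping transcripts
#'
#' Each peak is assigned to the same-strand annotated transcript with the
#' largest overlap (ties broken by overlap fraction of the transcript, then
#' lexicographic id). Peaks overlapping nothing are labelled intergenic.
#'
#' @param peaks Peak tibble with `start`, `end`, `strand`.
#' @param annotation Annotation tibble.
#' @return `peaks` with `target_id` (`NA` for intergenic peaks).
#' @export
assign_targets <- function(peaks, annotation) {
  peaks$target_id <- vapply(seq_len(nrow(peaks)), function(i) {
    s <- peaks$start[i]; e <- peaks$end[i]; st <- peaks$strand[i]
    ov <- pmin(e, annotation$end) - pmax(s, annotation$start)
    ok <- which(annotation$strand == st & ov > 0)
    if (length(ok) == 0) return(NA_character_)
    ovf <- ov[ok] / (annotation$end[ok] - annotation$start[ok])
    ord <- order(-ov[ok], -ovf, annotation$id[ok])
    annotation$id[ok][ord[1]]
  }, character(1))
  peaks
}

#' Set algebra over two target id sets
#'
#' @param targets_a,targets_b Character vectors of target ids (e.g. the
#'   RNAs bound by two different RNA-binding proteins).
#' @return Tibble with `only_a`, `only_b`, `both`; the three counts sum to
#'   the size of the union.
#' @export
overlap_sets <- function(targets_a, targets_b) {
  a <- unique(stats::na.omit(targets_a))
  b <- unique(stats::na.omit(targets_b))
  tibble::tibble(
    only_a = length(setdiff(a, b)),
    only_b = length(setdiff(b, a)),
    both = length(intersect(a, b))
  )
}

#' Classify peak positions along their target transcript
#'
#' The transcript length is normalized to `[0, 1]` in 5' to 3' orientation
#' (strand-aware) and the peak midpoint decides the class: `[0, 0.25)` is
#' `five_prime`, `[0.25, 0.75)` is `internal`, `[0.75, 1]` is
#' `three_prime`. Peaks without a target are `intergenic`.
#'
#' @param peaks Peak tibble with `start`, `end`, `strand` and `target_id`
#'   (from [assign_targets()]).
#' @param annotation Annotation tibble providing target coordinates.
#' @return `peaks` with `positional_class` and `relative_position` (the
#'   midpoint fraction, `NA` for intergenic).
#' @export
positional_class <- function(peaks, annotation) {
  idx <- match(peaks$target_id, annotation$id)
  frac <- rep(NA_real_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    j <- idx[i]
    if (is.na(j)) next
    len <- annotation$end[j] - annotation$start[j]
    if (len <= 0) stop("zero-length transcript: ", annotation$id[j])
    mid <- (peaks$start[i] + peaks$end[i]) / 2
    frac[i] <- if (annotation$strand[j] == "+") {
      (mid - annotation$start[j]) / len
    } else {
      (annotation$end[j] - mid) / len
    }
  }
  frac_cl <- pmin(pmax(frac, 0), 1)
  peaks$relative_position <- frac
  peaks$positional_class <- dplyr::case_when(
    is.na(frac) ~ "intergenic",
    frac_cl < 0.25 ~ "five_prime",
    frac_cl < 0.75 ~ "internal",
    TRUE ~ "three_prime"
  )
  peaks
}

#' Compare peak GC content against a sliding-window genome background
#'
#' The background is the GC fraction of every window of `window` nt starting
#' at 0 with step `step` (only full windows; their number is
#' `floor((L - window) / step) + 1`). Peak GC fractions are compared to the
#' background with a two-sided Mann-Whitney U test. RNA-chaperone binding
#' sites are typically U/A-rich, i.e. expected below the genome average.
#'
#' @param peaks Peak tibble with `start`, `end`.
#' @param genome Genome sequence.
#' @param window,step Sliding-window size and step in nt.
#' @param exclude_overlapping Drop background windows that overlap a peak.
#' @return A `gc_bg_test` object: list with `peak_gc`, `background_gc`,
#'   `n_windows`, `statistic`, `p_value`, `peak_median`,
#'   `background_median`. [generics::tidy()] and [generics::glance()]
#'   methods are provided.
#' @export
gc_background_test <- function(peaks, genome, window = 50, step = 25,
                               exclude_overlapping = FALSE) {
  genome <- as_dnastring(genome)
  L <- length(genome)
  if (L < window) stop("genome shorter than one background window")
  starts0 <- seq(0L, L - window, by = step)  # 0-based window starts
  v <- Biostrings::Views(genome, start = starts0 + 1L, width = window)
  bg <- as.numeric(
    Biostrings::letterFrequency(v, letters = "GC", as.prob = TRUE))
  if (exclude_overlapping && nrow(peaks) > 0) {
    drop <- vapply(starts0, function(s) {
      any(peaks$start < s + window & peaks$end > s)
    }, logical(1))
    bg <- bg[!drop]
  }
  if (nrow(peaks) == 0) stop("no peaks supplied to gc_background_test()")
  pv <- Biostrings::Views(genome, start = peaks$start + 1L,
                          width = peaks$end - peaks$start)
  pg <- as.numeric(
    Biostrings::letterFrequency(pv, letters = "GC", as.prob = TRUE))
  ht <- stats::wilcox.test(pg, bg, alternative = "two.sided", exact = FALSE)
  structure(
    list(peak_gc = pg, background_gc = bg, n_windows = length(starts0),
         statistic = unname(ht$statistic), p_value = ht$p.value,
         peak_median = stats::median(pg),
         background_median = stats::median(bg)),
    class = "gc_bg_test"
  )
}

#' @export
print.gc_bg_test <- function(x, ...) {
  cat(sprintf(
    "<gc_bg_test> %d peaks (median GC %.3f) vs %d background windows (median GC %.3f)\n  Mann-Whitney U = %.1f, two-sided p = %.3g\n",
    length(x$peak_gc), x$peak_median, length(x$background_gc),
    x$background_median, x$statistic, x$p_value))
  invisible(x)
}
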