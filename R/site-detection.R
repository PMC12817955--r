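#' Exact conditional binomial rate-ratio test for 5' end counts
#'
#' Tests whether the read-start count `k_a` observed in one library is
#' larger than expected given the count `k_b` in the other library and the
#' two library sizes. Conditional on the total `n = k_a + k_b`, under the
#' null hypothesis of equal per-library start rates `k_a` is
#' `Binomial(n, s_a / (s_a + s_b))`; the returned one-sided p-value is
#' `P(X >= k_a)`. With no evidence (`n = 0`) the p-value is 1.
#'
#' This is the decision rule behind TSS and TPS detection: a TSS is a
#' position significantly *enriched* in the +TEX library (TEX degrades
#' processed 5'-monophosphate ends, sparing triphosphorylated primary 5'
#' ends), and a TPS is the mirror image, detected by swapping the inputs.
#'
#' @param k_a Count in the library expected to be enriched (vectorized).
#' @param k_b Count in the other library (vectorized).
#' @param s_a,s_b Library sizes (total counts), > 0.
#' @return One-sided p-value(s) in `[0, 1]`.
#' @export
#' @examples
#' site_test(20, 0, 1e6, 1e6)   # = 0.5^20
#' site_test(5, 5, 1e6, 1e6)    # = 638/1024
site_test <- function(k_a, k_b, s_a, s_b) {
  if (any(k_a < 0) || any(k_b < 0)) stop("counts must be non-negative")
  if (any(s_a <= 0) || any(s_b <= 0)) stop("library sizes must be > 0")
  n <- k_a + k_b
  prob <- s_a / (s_a + s_b)
  stats::pbinom(k_a - 1, n, prob, lower.tail = FALSE)
}

#' Call TSSs (or, inverted, TPSs) from paired read-start tracks
#'
#' Every position with at least `min_reads` starts in the enriched library
#' and a [site_test()] p-value below `alpha` becomes a candidate. Candidate
#' positions within `group_gap` nt of each other on the same strand are
#' merged into one group, represented by the position with the maximal
#' enriched count (ties broken towards the most 5' position on the strand).
#' Replicates are summed per library before testing, so one p-value is
#' produced per position.
#'
#' The reported `score` is the library-size-normalized read-start count of
#' the enriched library at the site, scaled to starts per 1e7 total counts;
#' `delta` is the difference of the normalized counts of the two libraries.
#' Both feed [apply_site_filters()]. Library sizes are estimated from
#' background positions (those below `min_reads` in both libraries), which
#' keeps the null rate ratio free of composition bias from the site signal
#' itself.
#'
#' @param track_enriched,track_depleted A [strand_track()] or list of
#'   replicate tracks for the library expected to be enriched / depleted at
#'   the sites of interest (for TSSs: +TEX is enriched).
#' @param min_reads Minimum summed read starts in the enriched library.
#' @param alpha Candidate p-value cutoff (strict `<`).
#' @param group_gap Maximum distance (nt) between candidates merged into one
#'   group.
#' @param site_type Label stored in the output (`"TSS"` or `"TPS"`).
#' @return A tibble of site calls with columns `position` (0-based),
#'   `strand`, `k_enriched`, `k_depleted`, `score`, `delta`, `pvalue`,
#'   `site_type`, `tss_class` (filled by [classify_tss()], `"n/a"` here).
#' @export
call_sites <- function(track_enriched, track_depleted, min_reads = 10,
                       alpha = 1e-9, group_gap = 5, site_type = "TSS") {
  enr <- sum_tracks(track_enriched)
  dep <- sum_tracks(track_depleted)
  if (length(enr$counts) != length(dep$counts)) {
    stop("enriched and depleted tracks differ in length")
  }
  if (enr$strand != dep$strand) stop("tracks must be on the same strand")
  # Effective library sizes are estimated from background positions only
  # (neither library reaches min_reads there). Total counts would be
  # composition-biased: strong TSS signal concentrated in the +TEX library
  # inflates its total and shifts the conditional null away from the
  # background rate ratio -- the same argument that favours median-of-ratios
  # over total-count normalization in DE analysis.
  bg <- enr$counts < min_reads & dep$counts < min_reads
  s_enr <- sum(enr$counts[bg])
  s_dep <- sum(dep$counts[bg])
  if (s_enr == 0 || s_dep == 0) {  # degenerate tracks: fall back to totals
    s_enr <- enr$library_size
    s_dep <- dep$library_size
  }
  empty <- tibble::tibble(
    position = integer(), strand = character(), k_enriched = numeric(),
    k_depleted = numeric(), score = numeric(), delta = numeric(),
    pvalue = numeric(), site_type = character(), tss_class = character()
  )
  if (s_enr == 0) return(empty)
  cand <- which(enr$counts >= min_reads)
  if (length(cand) == 0) return(empty)
  k_a <- enr$counts[cand]
  k_b <- dep$counts[cand]
  p <- site_test(k_a, k_b, s_enr, max(s_dep, 1))
  keep <- p < alpha
  if (!any(keep)) return(empty)
  pos <- cand[keep] - 1L  # back to 0-based
  rep_idx <- group_candidates(pos, k_a[keep], enr$strand, group_gap)
  pos0 <- pos[rep_idx]
  ord <- order(pos0)
  i <- pos0[ord] + 1L
  norm_enr <- enr$counts[i] / s_enr * 1e7
  norm_dep <- if (s_dep > 0) dep$counts[i] / s_dep * 1e7 else 0
  tibble::tibble(
    position = pos0[ord],
    strand = enr$strand,
    k_enriched = enr$counts[i],
    k_depleted = dep$counts[i],
    score = norm_enr,
    delta = norm_enr - norm_dep,
    pvalue = p[keep][rep_idx][ord],
    site_type = site_type,
    tss_class = "n/a"
  )
}

# Chain-merge candidate positions: successive candidates at distance
# <= gap belong to one group. Returns the index (into `pos`) of each
# group's representative: max count, tie -> most 5' on the strand
# (smallest position on "+", largest on "-").
group_candidates <- function(pos, counts, strand, gap) {
  ord <- order(pos)
  pos_s <- pos[ord]
  grp <- cumsum(c(1L, as.integer(diff(pos_s) > gap)))
  vapply(split(seq_along(pos_s), grp), function(ix) {
    cnt <- counts[ord[ix]]
    best <- ix[cnt == max(cnt)]
    pick <- if (strand == "+") best[1] else best[length(best)]
    ord[pick]
  }, integer(1), USE.NAMES = FALSE)
}

#' @describeIn call_sites TPS calling: identical to `call_sites()` with the
#'   +TEX and -TEX inputs inverted, so that 5' ends *depleted* after TEX
#'   treatment (processed, 5'-monophosphorylated ends) are detected.
#' @param track_plus_tex,track_minus_tex +TEX / -TEX read-start tracks
#'   (single tracks or replicate lists).
#' @export
call_tps <- function(track_plus_tex, track_minus_tex, min_reads = 10,
                     alpha = 1e-9, group_gap = 5) {
  call_sites(track_minus_tex, track_plus_tex, min_reads = min_reads,
             alpha = alpha, group_gap = group_gap, site_type = "TPS")
}

#' Filter site calls on score, positional difference and p-value
#'
#' Keeps calls with `score >= min_score`, `delta >= min_delta` and
#' `pvalue <= max_p`; all three thresholds are inclusive.
#'
#' @param calls Site-call tibble from [call_sites()].
#' @param min_score Minimum normalized enriched count.
#' @param min_delta Minimum normalized count difference between libraries.
#' @param max_p Maximum p-value.
#' @return The filtered tibble.
#' @export
apply_site_filters <- function(calls, min_score = 600, min_delta = 10,
                               max_p = 0.05) {
  dplyr::filter(calls, .data$score >= min_score, .data$delta >= min_delta,
                .data$pvalue <= max_p)
}

#' Classify TSS calls relative to annotated genes
#'
#' Assigns the five positional classes used for archaeal dRNA-seq maps:
#' * `pTSS` - within `upstream_window` nt upstream of a same-strand gene
#'   start and the closest such call to that start;
#' * `UTR` - within the window but not the closest;
#' * `iTSS` - inside a same-strand gene body;
#' * `aTSS` - inside an opposite-strand gene or within `antisense_flank` nt
#'   of its boundaries;
#' * `oTSS` - orphan, none of the above.
#' A call matching several rules takes the first class in the order
#' pTSS > UTR > iTSS > aTSS > oTSS.
#'
#' @param calls Site-call tibble.
#' @param annotation Annotation tibble (genes; rows with `type == "gene"`
#'   are used if the column exists).
#' @param genome_length Genome length for bounds checking (optional).
#' @param upstream_window Upstream window (nt) for pTSS/UTR assignment.
#' @param antisense_flank Flank (nt) around opposite-strand genes counted as
#'   antisense.
#' @return `calls` with `tss_class` filled in.
#' @export
classify_tss <- function(calls, annotation, genome_length = NULL,
                         upstream_window = 300, antisense_flank = 100) {
  genes <- annotation
  if ("type" %in% names(genes)) genes <- genes[genes$type == "gene", ]
  if (!is.null(genome_length) &&
      any(calls$position < 0 | calls$position >= genome_length)) {
    stop("site call position outside genome bounds")
  }
  if (nrow(calls) == 0) return(calls)
  n <- nrow(calls)
  # distance from each call to each same-strand gene start (5' end)
  g5 <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  upstream_gene <- rep(NA_integer_, n)
  upstream_dist <- rep(NA_integer_, n)
  inside_same <- logical(n)
  inside_anti <- logical(n)
  for (i in seq_len(n)) {
    p <- calls$position[i]
    st <- calls$strand[i]
    same <- genes$strand == st
    d <- ifelse(genes$strand == "+", g5 - p, p - g5)
    ok <- same & d >= 0 & d <= upstream_window
    if (any(ok)) {
      j <- which(ok)[which.min(d[ok])]
      upstream_gene[i] <- j
      upstream_dist[i] <- d[j]
    }
    inside_same[i] <- any(same & p >= genes$start & p < genes$end)
    inside_anti[i] <- any(!same & p >= genes$start - antisense_flank &
                            p < genes$end + antisense_flank)
  }
  # per gene start, the closest in-window call is primary
  cls <- rep(NA_character_, n)
  in_window <- !is.na(upstream_gene)
  for (j in unique(upstream_gene[in_window])) {
    ix <- which(upstream_gene == j)
    primary <- ix[which.min(upstream_dist[ix])]
    cls[primary] <- "pTSS"
    cls[setdiff(ix, primary)] <- "UTR"
  }
  cls[is.na(cls) & inside_same] <- "iTSS"
  cls[is.na(cls) & inside_anti] <- "aTSS"
  cls[is.na(cls)] <- "oTSS"
  calls$tss_class <- cls
  calls
}

#' Extract flanking sequences around site calls
#'
#' Returns the `2 * flank + 1` nt window centred on each site, reverse
#' complemented for minus-strand sites so the site position is always index
#' `flank` (0-based) reading 5' to 3'. Sites closer than `flank` to a genome
#' edge yield a truncated sequence with `truncated = TRUE`.
#'
#' @param calls Site-call tibble.
#' @param genome Genome sequence (`DNAString`, `DNAStringSet` or character).
#' @param flank Flank length in nt on each side.
#' @return Tibble with `position`, `strand`, `sequence`, `truncated`.
#' @export
extract_flanks <- function(calls, genome, flank = 10) {
  genome <- as_dnastring(genome)
  L <- length(genome)
  purrr::pmap_dfr(
    list(calls$position, calls$strand),
    function(p, st) {
      lo <- max(0L, p - flank)
      hi <- min(L, p + flank + 1L)
      tibble::tibble(
        position = p, strand = st,
        sequence = extract_genome_seq(genome, lo, hi, st),
        truncated = (hi - lo) < (2 * flank + 1)
      )
    }
  )
}
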