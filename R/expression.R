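#' Transcripts-per-million normalization
#'
#' `TPM_i = 1e6 * (c_i / l_i) / sum_j (c_j / l_j)`; every TPM vector sums to
#' 1e6 (all-zero input stays all-zero rather than dividing by zero).
#'
#' @param counts Numeric vector or matrix (features x samples) of read
#'   counts.
#' @param lengths Feature lengths in nt (> 0), recycled over columns for a
#'   matrix.
#' @return TPM values with the shape of `counts`.
#' @export
#' @examples
#' tpm(c(10, 10), c(100, 200))
tpm <- function(counts, lengths) {
  if (any(lengths <= 0)) stop("feature lengths must be > 0")
  f <- function(v) {
    r <- v / lengths
    s <- sum(r)
    if (s == 0) return(r)
    1e6 * r / s
  }
  if (is.matrix(counts)) apply(counts, 2, f) else f(counts)
}

#' @describeIn tpm `log2(TPM + 1)`, the usual abundance scale for
#'   cross-library comparisons.
#' @export
log_tpm <- function(counts, lengths) log2(tpm(counts, lengths) + 1)

#' Simple differential-expression stand-in
#'
#' A documented, self-contained replacement for a full count-model DE fit,
#' for use where external DESeq2-style tables are not available: size
#' factors are estimated by the median-of-ratios method across all samples,
#' the log2 fold change is the ratio of mean normalized counts (pseudocount
#' 0.5), and per-feature p-values come from a pooled-variance two-sample
#' t-test on log2 normalized counts (well calibrated at the 2-3 replicates
#' this targets, where Welch's correction is markedly conservative),
#' adjusted with Benjamini-Hochberg. A feature is
#' flagged significant when `|log2fc| >= lfc_threshold` and
#' `pvalue < p_threshold` (raw p, matching the common reporting convention
#' for these thresholds). Externally produced fold-change tables can be
#' used anywhere this output is consumed (see
#' [read_fold_change_table()]).
#'
#' @param counts_a,counts_b Count matrices (features x replicates, shared
#'   rownames; >= 2 replicates each). The reported fold change is B over A.
#' @param lfc_threshold,p_threshold Significance thresholds.
#' @return A `de_result`: tibble with `feature_id`, `base_mean`, `log2fc`,
#'   `pvalue`, `padj`, `significant`; size factors in
#'   `attr(, "size_factors")`.
#' @export
de_stand_in <- function(counts_a, counts_b, lfc_threshold = 1,
                        p_threshold = 0.05) {
  counts_a <- as.matrix(counts_a)
  counts_b <- as.matrix(counts_b)
  if (is.null(rownames(counts_a)) || is.null(rownames(counts_b))) {
    stop("count matrices need rownames (feature ids)")
  }
  if (!identical(rownames(counts_a), rownames(counts_b))) {
    stop("feature sets of the two groups differ")
  }
  if (ncol(counts_a) < 2 || ncol(counts_b) < 2) {
    stop("need >= 2 replicates per group")
  }
  all_counts <- cbind(counts_a, counts_b)
  sf <- size_factors(all_counts)
  na <- ncol(counts_a)
  norm <- sweep(all_counts, 2, sf, "/")
  norm_a <- norm[, seq_len(na), drop = FALSE]
  norm_b <- norm[, -seq_len(na), drop = FALSE]
  mean_a <- rowMeans(norm_a)
  mean_b <- rowMeans(norm_b)
  log_a <- log2(norm_a + 0.5)
  log_b <- log2(norm_b + 0.5)
  pvals <- vapply(seq_len(nrow(norm)), function(i) {
    a <- log_a[i, ]; b <- log_b[i, ]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else NA_real_)
    }
    stats::t.test(a, b, var.equal = TRUE)$p.value
  }, numeric(1))
  out <- tibble::tibble(
    feature_id = rownames(all_counts),
    base_mean = rowMeans(norm),
    log2fc = log2((mean_b + 0.5) / (mean_a + 0.5)),
    pvalue = pvals,
    padj = stats::p.adjust(pvals, method = "BH")
  )
  out$significant <- !is.na(out$pvalue) &
    abs(out$log2fc) >= lfc_threshold & out$pvalue < p_threshold
  attr(out, "size_factors") <- sf
  class(out) <- c("de_result", class(out))
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median, over features with a
#' positive geometric mean across samples, of the count over that geometric
#' mean.
#'
#' @param counts Count matrix (features x samples).
#' @return Numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use)) stop("no feature has all-positive counts; cannot estimate size factors")
  apply(counts, 2, function(col) {
    exp(stats::median(log(col[use]) - log_gm[use]))
  })
}

#' Build antisense/mRNA pairs from an annotation
#'
#' A pair exists for every (gene, asRNA) combination where the asRNA
#' overlaps the gene on the opposite strand by at least 1 nt; genes with
#' several asRNAs appear in several pairs.
#'
#' @param annotation Annotation tibble holding rows with `type == "gene"`
#'   and `type == "asRNA"`.
#' @return Tibble with `mrna_id`, `asrna_id`, `overlap_nt`.
#' @export
build_pairs <- function(annotation) {
  genes <- annotation[annotation$type == "gene", ]
  as_rnas <- annotation[annotation$type == "asRNA", ]
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(as_rnas$start + 1L, as_rnas$end),
    IRanges::IRanges(genes$start + 1L, genes$end)
  )
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  anti <- as_rnas$strand[qi] != genes$strand[si]
  qi <- qi[anti]; si <- si[anti]
  tibble::tibble(
    mrna_id = genes$id[si],
    asrna_id = as_rnas$id[qi],
    overlap_nt = pmin(as_rnas$end[qi], genes$end[si]) -
      pmax(as_rnas$start[qi], genes$start[si])
  )
}

#' Pearson correlation of paired fold-change vectors across contrasts
#'
#' For each pair, the log2 fold changes of the mRNA and the asRNA are
#' matched by contrast; the Pearson correlation is computed over contrasts
#' where both values are finite. Pairs with fewer than 3 shared contrasts,
#' or a zero-variance vector, get a missing PCC (not 0: Pearson is
#' undefined there) and class `uncorrelated`. Classes use inclusive
#' thresholds: `positive` for `pcc >= threshold`, `negative` for
#' `pcc <= -threshold`.
#'
#' @param pairs Pair tibble from [build_pairs()] (or any tibble with
#'   `mrna_id`, `asrna_id`).
#' @param lfc_mrna,lfc_asrna Long fold-change tibbles with `feature_id`,
#'   `contrast_id`, `log2fc`.
#' @param pcc_threshold Class threshold (default 0.5).
#' @return `pairs` with `pcc`, `n_contrasts_used`, `corr_class`.
#' @export
pair_pcc <- function(pairs, lfc_mrna, lfc_asrna, pcc_threshold = 0.5) {
  m_split <- split(lfc_mrna[, c("contrast_id", "log2fc")], lfc_mrna$feature_id)
  a_split <- split(lfc_asrna[, c("contrast_id", "log2fc")], lfc_asrna$feature_id)
  res <- purrr::map2_dfr(pairs$mrna_id, pairs$asrna_id, function(mid, aid) {
    m <- m_split[[mid]]
    a <- a_split[[aid]]
    if (is.null(m) || is.null(a)) {
      return(tibble::tibble(pcc = NA_real_, n_contrasts_used = 0L))
    }
    shared <- intersect(m$contrast_id, a$contrast_id)
    x <- m$log2fc[match(shared, m$contrast_id)]
    y <- a$log2fc[match(shared, a$contrast_id)]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(pcc = NA_real_, n_contrasts_used = length(x)))
    }
    tibble::tibble(pcc = stats::cor(x, y), n_contrasts_used = length(x))
  })
  out <- dplyr::bind_cols(pairs, res)
  out$corr_class <- dplyr::case_when(
    is.na(out$pcc) ~ "uncorrelated",
    out$pcc >= pcc_threshold ~ "positive",
    out$pcc <= -pcc_threshold ~ "negative",
    TRUE ~ "uncorrelated"
  )
  out
}

#' Direction agreement of correlated pairs per timepoint
#'
#' Among pairs passing the correlation filter (`|pcc| >= pcc_threshold`),
#' counts whether the mRNA and asRNA fold changes at each timepoint move in
#' the same or in opposite directions. Pairs where either fold change is
#' exactly 0 (sign undefined) or missing are excluded from the
#' denominator. Percentages are over included pairs and always sum to 100.
#'
#' @param pairs Pair tibble with `pcc` (from [pair_pcc()]).
#' @param lfc_mrna,lfc_asrna Long fold-change tibbles with `feature_id`,
#'   `timepoint` (or `contrast_id`), `log2fc`.
#' @param pcc_threshold Correlation filter threshold.
#' @return Tibble with `timepoint`, `n_pairs`, `pct_same`, `pct_opposite`.
#' @export
direction_agreement <- function(pairs, lfc_mrna, lfc_asrna,
                                pcc_threshold = 0.5) {
  tp_col <- if ("timepoint" %in% names(lfc_mrna)) "timepoint" else "contrast_id"
  use <- pairs[!is.na(pairs$pcc) & abs(pairs$pcc) >= pcc_threshold, ]
  tps <- sort(unique(lfc_mrna[[tp_col]]))
  out <- purrr::map_dfr(tps, function(tp) {
    m <- lfc_mrna[lfc_mrna[[tp_col]] == tp, ]
    a <- lfc_asrna[lfc_asrna[[tp_col]] == tp, ]
    x <- m$log2fc[match(use$mrna_id, m$feature_id)]
    y <- a$log2fc[match(use$asrna_id, a$feature_id)]
    ok <- is.finite(x) & is.finite(y) & x != 0 & y != 0
    n <- sum(ok)
    if (n == 0) stop("no pairs with defined directions at timepoint ", tp)
    same <- sum(sign(x[ok]) * sign(y[ok]) > 0)
    pct_same <- 100 * same / n
    tibble::tibble(timepoint = tp, n_pairs = n,
                   pct_same = pct_same,
                   pct_opposite = 100 - pct_same)
  })
  out
}

#' Joint classification of asRNA, mRNA and protein fold changes
#'
#' Classifies each molecule of every pair as up, down or unchanged using
#' `|log2fc| >= lfc_threshold` with `pvalue < p_threshold` (missing p-values
#' never qualify as changed), then tabulates the marginal percentages per
#' molecule and the joint asRNA/protein categories. Pairs without a protein
#' value are excluded and their count reported.
#'
#' @param pairs Pair tibble (`mrna_id`, `asrna_id`).
#' @param lfc_asrna,lfc_mrna,lfc_protein Single-contrast fold-change
#'   tibbles with `feature_id`, `log2fc`, `pvalue`. Protein values are
#'   keyed by the mRNA id.
#' @param lfc_threshold,p_threshold Change thresholds (RNA thresholds are
#'   reused for the protein table; override if dedicated proteomics cutoffs
#'   exist).
#' @return A list: `categories` (per-pair tibble with `asrna_change`,
#'   `mrna_change`, `protein_change`, `joint_category`), `summary`
#'   (percentage tibble per molecule and direction), `n_excluded`.
#' @export
protein_integration <- function(pairs, lfc_asrna, lfc_mrna, lfc_protein,
                                lfc_threshold = 1, p_threshold = 0.05) {
  classify <- function(tbl, ids) {
    i <- match(ids, tbl$feature_id)
    lfc <- tbl$log2fc[i]
    p <- tbl$pvalue[i]
    changed <- !is.na(lfc) & !is.na(p) & abs(lfc) >= lfc_threshold &
      p < p_threshold
    dplyr::case_when(
      is.na(lfc) ~ NA_character_,
      changed & lfc > 0 ~ "up",
      changed & lfc < 0 ~ "down",
      TRUE ~ "unchanged"
    )
  }
  cats <- tibble::tibble(
    mrna_id = pairs$mrna_id,
    asrna_id = pairs$asrna_id,
    asrna_change = classify(lfc_asrna, pairs$asrna_id),
    mrna_change = classify(lfc_mrna, pairs$mrna_id),
    protein_change = classify(lfc_protein, pairs$mrna_id)
  )
  n_excluded <- sum(is.na(cats$protein_change))
  cats <- cats[!is.na(cats$protein_change), ]
  cats$joint_category <- paste0("asRNA-", cats$asrna_change,
                                "/protein-", cats$protein_change)
  n <- nrow(cats)
  summarise_mol <- function(col, molecule) {
    tibble::tibble(
      molecule = molecule,
      direction = c("up", "down", "unchanged"),
      pct = vapply(c("up", "down", "unchanged"), function(d) {
        if (n == 0) 0 else 100 * sum(cats[[col]] == d, na.rm = TRUE) / n
      }, numeric(1), USE.NAMES = FALSE)
    )
  }
  list(
    categories = cats,
    summary = dplyr::bind_rows(
      summarise_mol("asrna_change", "asRNA"),
      summarise_mol("mrna_change", "mRNA"),
      summarise_mol("protein_change", "protein")
    ),
    n_excluded = n_excluded
  )
}

#' Mean fold-change trajectories of bound versus unbound transcripts
#'
#' Partitions the transcript universe into four groups by RIP-seq binding
#' status (bound by protein A only, by protein B only, by both, unbound)
#' and summarizes each group's log2 fold change per timepoint (mean and
#' standard error), testing every bound group against the unbound group
#' with a two-sided Mann-Whitney U test, Benjamini-Hochberg adjusted within
#' each timepoint. Significance tiers follow the usual asterisk convention
#' (`*` p < 0.05, `***` p < 0.005).
#'
#' @param targets_a,targets_b Character vectors of bound target ids.
#' @param lfc Long fold-change tibble with `feature_id`, `timepoint` (or
#'   `contrast_id`), `log2fc`.
#' @param universe Character vector of all transcript ids; defaults to the
#'   features present in `lfc`.
#' @param group_a,group_b Labels for the two proteins.
#' @return Tibble with `timepoint`, `group`, `n`, `mean_log2fc`, `se`,
#'   `p_vs_unbound`, `padj_vs_unbound`, `signif`.
#' @export
smap_group_trajectories <- function(targets_a, targets_b, lfc,
                                    universe = unique(lfc$feature_id),
                                    group_a = "smap1", group_b = "smap2") {
  tp_col <- if ("timepoint" %in% names(lfc)) "timepoint" else "contrast_id"
  a <- intersect(unique(targets_a), universe)
  b <- intersect(unique(targets_b), universe)
  groups <- list(
    setdiff(a, b), setdiff(b, a), intersect(a, b),
    setdiff(universe, union(a, b))
  )
  names(groups) <- c(paste0(group_a, "_only"), paste0(group_b, "_only"),
                     "both", "unbound")
  empty <- vapply(groups, length, integer(1)) == 0
  if (any(empty)) {
    warning("empty group(s) skipped: ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  out <- purrr::map_dfr(sort(unique(lfc[[tp_col]])), function(tp) {
    sl <- lfc[lfc[[tp_col]] == tp, ]
    vals <- lapply(groups, function(ids) {
      v <- sl$log2fc[match(ids, sl$feature_id)]
      v[is.finite(v)]
    })
    unb <- vals[["unbound"]]
    rows <- purrr::imap_dfr(vals, function(v, g) {
      p <- if (g != "unbound" && !is.null(unb) && length(unb) > 0 &&
               length(v) > 0) {
        stats::wilcox.test(v, unb, exact = FALSE)$p.value
      } else {
        NA_real_
      }
      tibble::tibble(timepoint = tp, group = g, n = length(v),
                     mean_log2fc = mean(v),
                     se = stats::sd(v) / sqrt(length(v)),
                     p_vs_unbound = p)
    })
    rows$padj_vs_unbound <- stats::p.adjust(rows$p_vs_unbound, method = "BH")
    rows
  })
  out$signif <- dplyr::case_when(
    is.na(out$padj_vs_unbound) ~ "",
    out$padj_vs_unbound < 0.005 ~ "***",
    out$padj_vs_unbound < 0.05 ~ "*",
    TRUE ~ "ns"
  )
  out
}
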