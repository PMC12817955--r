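#' Simulate a genome with non-overlapping gene models
#'
#' Draws an i.i.d. base sequence with a target GC fraction and places
#' non-overlapping gene models on both strands. The defaults are a
#' desk-scale stand-in for a small, AT-rich archaeal chromosome (100 kb,
#' 60 genes, GC 0.37).
#'
#' @param length Genome length in nt (>= 1000).
#' @param gc_fraction Expected GC content in `(0, 1)`; the degenerate values
#'   0 and 1 are allowed and give pure-AT / pure-GC sequences.
#' @param n_genes Number of gene models to place.
#' @param gene_length_range Min/max gene length in nt.
#' @param seed Integer seed; identical seeds give byte-identical output.
#'
#' @return A list with `sequence` (a `DNAString`) and `genes` (an annotation
#'   tibble with columns `id`, `type`, `start`, `end`, `strand`).
#' @export
#' @examples
#' g <- make_genome(length = 10000, n_genes = 8, seed = 1)
#' g$genes
make_genome <- function(length = 100000L, gc_fraction = 0.37, n_genes = 60L,
                        gene_length_range = c(300L, 1500L), seed = 1L) {
  length <- as.integer(length)
  if (length < 1000L) stop("genome length must be >= 1000 nt")
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0, 1]")
  withr::with_seed(seed, {
    base_p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
                G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    seq <- paste(sample(names(base_p), length, replace = TRUE, prob = base_p),
                 collapse = "")
    genes <- place_genes(length, n_genes, gene_length_range)
  })
  list(sequence = Biostrings::DNAString(seq), genes = genes)
}

# Non-overlapping placement by partitioning the genome into slots.
place_genes <- function(genome_length, n_genes, len_range) {
  n_genes <- as.integer(n_genes)
  if (n_genes == 0L) {
    return(tibble::tibble(id = character(), type = character(),
                          start = integer(), end = integer(),
                          strand = character()))
  }
  slot <- genome_length %/% n_genes
  if (slot <= len_range[1] + 2L) {
    stop(sprintf(
      "genome of %d nt is too small to place %d non-overlapping genes of >= %d nt",
      genome_length, n_genes, len_range[1]))
  }
  max_len <- min(len_range[2], slot - 2L)
  lens <- sample(seq(len_range[1], max_len), n_genes, replace = TRUE)
  offsets <- vapply(slot - lens - 1L, function(m) sample.int(m, 1L), integer(1))
  starts <- (seq_len(n_genes) - 1L) * slot + offsets
  tibble::tibble(
    id = sprintf("gene_%03d", seq_len(n_genes)),
    type = "gene",
    start = as.integer(starts),
    end = as.integer(starts + lens),
    strand = sample(c("+", "-"), n_genes, replace = TRUE)
  )
}

#' Assemble a synthetic ground truth for a full pipeline run
#'
#' Plants TEX-enriched TSSs, TEX-depleted TPSs, RIP-seq enrichment peaks,
#' Term-seq TTSs paired with antisense/orphan TSSs, and correlated
#' asRNA/mRNA fold-change pairs on a simulated genome. Planted site
#' positions are kept at least `2 * group_gap` apart on the same strand so
#' that detection groups are unambiguous.
#'
#' @param genome Output of [make_genome()]; generated if `NULL`.
#' @param n_tss,n_tps Numbers of planted TSS / TPS positions.
#' @param enrichment_ratio +TEX/-TEX mean ratio at planted TSSs (> 1).
#' @param depletion_ratio -TEX/+TEX mean ratio at planted TPSs (> 1).
#' @param n_peaks,peak_width,peak_log2fc RIP-seq peak truth.
#' @param n_pairs,true_pcc asRNA/mRNA pair truth; `true_pcc` is recycled
#'   over pairs.
#' @param n_transcripts Number of planted antisense transcripts (aTSS + TTS
#'   within the matching window) used by annotation-recovery tests.
#' @param seed Integer seed.
#'
#' @return A `synthetic_truth` list with the genome, the planted feature
#'   tibbles and the seed. See [write_truth()] for the on-disk manifest.
#' @export
make_truth <- function(genome = NULL, n_tss = 200L, n_tps = 100L,
                       enrichment_ratio = 5, depletion_ratio = 5,
                       n_peaks = 40L, peak_width = 30L, peak_log2fc = 2,
                       n_pairs = 100L, true_pcc = 0.5, n_transcripts = 25L,
                       seed = 1L) {
  if (any(enrichment_ratio <= 1) || any(depletion_ratio <= 1)) {
    stop("enrichment/depletion ratios must be > 1")
  }
  if (any(abs(true_pcc) > 1)) stop("true_pcc must be in [-1, 1]")
  if (is.null(genome)) genome <- make_genome(seed = seed)
  L <- length(genome$sequence)
  withr::with_seed(seed + 1000L, {
    tss <- plant_positions(L, n_tss, min_dist = 12L)
    tps <- plant_positions(L, n_tps, min_dist = 12L, avoid = tss)
    peaks <- plant_intervals(L, n_peaks, peak_width)
    peaks$true_log2fc <- peak_log2fc
    pair_truth <- tibble::tibble(
      mrna_id = sprintf("mrna_%03d", seq_len(n_pairs)),
      asrna_id = sprintf("asrna_%03d", seq_len(n_pairs)),
      true_pcc = rep_len(true_pcc, n_pairs)
    )
    transcripts <- plant_transcripts(genome$genes, L, n_transcripts)
  })
  tss$enrichment_ratio <- enrichment_ratio
  tps$depletion_ratio <- depletion_ratio
  structure(
    list(genome = genome, genome_length = L,
         planted_tss = tss, planted_tps = tps, planted_peaks = peaks,
         pair_truth = pair_truth, planted_transcripts = transcripts,
         seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

plant_positions <- function(L, n, min_dist = 12L, avoid = NULL) {
  if (n == 0L) {
    return(tibble::tibble(position = integer(), strand = character()))
  }
  # lay candidates on a coarse grid, then jitter: guarantees min distance
  margin <- 200L
  grid <- seq(margin, L - margin, by = max(min_dist * 4L, 50L))
  if (length(grid) < n + NROW(avoid)) {
    stop("genome too short to plant ", n, " separated positions")
  }
  taken <- if (is.null(avoid)) integer() else avoid$position
  free <- grid[!grid %in% taken]
  pos <- sort(sample(free, n))
  tibble::tibble(position = as.integer(pos),
                 strand = sample(c("+", "-"), n, replace = TRUE))
}

plant_intervals <- function(L, n, width) {
  if (width < 1L) stop("peak width must be >= 1 nt")
  if (n == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character()))
  }
  slot <- (L - 400L) %/% n
  if (slot <= width + 20L) stop("genome too short for ", n, " peaks of ", width, " nt")
  starts <- 200L + (seq_len(n) - 1L) * slot +
    vapply(rep(slot - width - 10L, n), function(m) sample.int(m, 1L), integer(1))
  tibble::tibble(start = as.integer(starts),
                 end = as.integer(starts + width),
                 strand = sample(c("+", "-"), n, replace = TRUE))
}

# Planted antisense transcripts: an aTSS inside an opposite-strand gene plus
# a TTS at a known downstream distance <= 400 nt. One transcript per
# alternating long gene, so planted TSS/TTS pairs are separated by more than
# the matching window and recovery by window matching is unambiguous; n is
# silently capped by the number of usable genes.
plant_transcripts <- function(genes, L, n) {
  empty <- tibble::tibble(id = character(), tss = integer(), tts = integer(),
                          start = integer(), end = integer(),
                          strand = character())
  if (n == 0L || nrow(genes) == 0L) return(empty)
  long <- genes[genes$end - genes$start >= 500L, ]
  long <- long[order(long$start), ]
  usable <- long[seq(1L, nrow(long), by = 2L), , drop = FALSE]
  n <- min(n, nrow(usable))
  if (n == 0L) return(empty)
  usable <- usable[seq_len(n), ]
  glen <- usable$end - usable$start
  d <- vapply(pmin(380L, glen - 40L), function(m) {
    sample(100:m, 1L)
  }, integer(1))
  as_strand <- ifelse(usable$strand == "+", "-", "+")
  tss <- ifelse(as_strand == "+", usable$start + 20L, usable$end - 21L)
  tts <- ifelse(as_strand == "+", tss + d, tss - d)
  start <- as.integer(pmin(tss, tts))
  end <- as.integer(pmax(tss, tts)) + 1L
  tibble::tibble(
    id = sprintf("planted_as_%03d", seq_len(n)),
    tss = as.integer(tss), tts = as.integer(tts),
    start = start, end = end, strand = as_strand
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d nt genome, %d genes | %d TSS, %d TPS, %d peaks, %d pairs (seed %d)\n",
    x$genome_length, nrow(x$genome$genes), nrow(x$planted_tss),
    nrow(x$planted_tps), nrow(x$planted_peaks), nrow(x$pair_truth), x$seed))
  invisible(x)
}

#' Write / read the planted-truth manifest
#'
#' Serializes every planted feature as plain TSV so that coordinates survive
#' a write/read round trip unchanged.
#'
#' @param truth A `synthetic_truth` object.
#' @param dir Directory for the manifest files.
#' @return `write_truth()` returns `dir` invisibly; `read_truth()` returns a
#'   list of tibbles keyed by feature class.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  parts <- c("planted_tss", "planted_tps", "planted_peaks", "pair_truth",
             "planted_transcripts")
  for (p in parts) {
    readr::write_tsv(truth[[p]], file.path(dir, paste0(p, ".tsv")))
  }
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  parts <- c("planted_tss", "planted_tps", "planted_peaks", "pair_truth",
             "planted_transcripts")
  out <- lapply(parts, function(p) {
    readr::read_tsv(file.path(dir, paste0(p, ".tsv")), show_col_types = FALSE,
                    progress = FALSE)
  })
  names(out) <- parts
  out
}

#' Simulate paired +/-TEX dRNA-seq read-start tracks
#'
#' Per-position read-start counts are Poisson. Away from planted sites both
#' libraries share the background rate. At a planted TSS the -TEX mean is
#' `depth` and the +TEX mean is `enrichment_ratio * depth`; at a planted TPS
#' the roles are swapped (+TEX mean `depth`, -TEX mean
#' `depletion_ratio * depth`), which is exactly the signal the inverted-input
#' TPS caller looks for.
#'
#' @param truth A `synthetic_truth`.
#' @param depth Mean read starts per planted site in the *depleted* library.
#' @param background_rate Mean read starts per nt elsewhere.
#' @param n_reps Replicates per library (default 2, a typical dRNA-seq
#'   design).
#' @param seed Integer seed; defaults to the truth's seed.
#'
#' @return A nested list `tracks[[strand]][[library]]` with
#'   `library` in `minus_tex`, `plus_tex`; each element is a list of
#'   [strand_track()] replicates.
#' @export
simulate_drna_tracks <- function(truth, depth = 10, background_rate = 0.5,
                                 n_reps = 2L, seed = truth$seed) {
  stopifnot(depth > 0, background_rate >= 0)
  L <- truth$genome_length
  warn_close_sites(truth)
  withr::with_seed(seed + 2000L, {
    out <- list()
    for (st in c("+", "-")) {
      mean_minus <- rep(background_rate, L)
      mean_plus <- rep(background_rate, L)
      tss <- truth$planted_tss[truth$planted_tss$strand == st, ]
      tps <- truth$planted_tps[truth$planted_tps$strand == st, ]
      # TSS: enriched in +TEX
      mean_minus[tss$position + 1L] <- depth
      mean_plus[tss$position + 1L] <- depth * tss$enrichment_ratio
      # TPS: depleted in +TEX
      mean_plus[tps$position + 1L] <- depth
      mean_minus[tps$position + 1L] <- depth * tps$depletion_ratio
      key <- if (st == "+") "plus" else "minus"
      out[[key]] <- list(
        minus_tex = lapply(seq_len(n_reps), function(r) {
          strand_track(stats::rpois(L, mean_minus), st, "minus_tex", r)
        }),
        plus_tex = lapply(seq_len(n_reps), function(r) {
          strand_track(stats::rpois(L, mean_plus), st, "plus_tex", r)
        })
      )
    }
    out
  })
}

warn_close_sites <- function(truth, gap = 5L) {
  sites <- rbind(
    truth$planted_tss[, c("position", "strand")],
    truth$planted_tps[, c("position", "strand")]
  )
  for (st in c("+", "-")) {
    p <- sort(sites$position[sites$strand == st])
    if (length(p) > 1 && any(diff(p) <= gap)) {
      warning("planted sites closer than the grouping gap on strand ", st)
    }
  }
  invisible(NULL)
}

#' Simulate RIP-seq coIP and mock coverage tracks
#'
#' Mock coverage is Poisson with mean `depth` everywhere; inside planted
#' peaks the coIP mean is `depth * 2^true_log2fc`, outside it equals the
#' mock mean.
#'
#' @param truth A `synthetic_truth`.
#' @param depth Mean per-position coverage.
#' @param n_reps Replicates per arm (default 3, a typical RIP-seq design).
#' @param seed Integer seed; defaults to the truth's seed.
#' @return A nested list `tracks[[strand]][[arm]]` with arms `coip` and
#'   `mock`, each a list of [strand_track()] replicates.
#' @export
simulate_ripseq <- function(truth, depth = 50, n_reps = 3L,
                            seed = truth$seed) {
  stopifnot(n_reps >= 1)
  if (nrow(truth$planted_peaks) > 0 &&
      any(truth$planted_peaks$end - truth$planted_peaks$start < 1)) {
    stop("planted peaks must be at least 1 nt wide")
  }
  L <- truth$genome_length
  withr::with_seed(seed + 3000L, {
    out <- list()
    for (st in c("+", "-")) {
      mean_coip <- rep(depth, L)
      pk <- truth$planted_peaks[truth$planted_peaks$strand == st, ]
      for (i in seq_len(nrow(pk))) {
        idx <- (pk$start[i] + 1L):pk$end[i]
        mean_coip[idx] <- depth * 2^pk$true_log2fc[i]
      }
      key <- if (st == "+") "plus" else "minus"
      out[[key]] <- list(
        coip = lapply(seq_len(n_reps), function(r) {
          strand_track(stats::rpois(L, mean_coip), st, "coip", r)
        }),
        mock = lapply(seq_len(n_reps), function(r) {
          strand_track(stats::rpois(L, depth), st, "mock", r)
        })
      )
    }
    out
  })
}

#' Simulate correlated mRNA/asRNA fold-change tables
#'
#' For each pair, the (mRNA, asRNA) log2 fold changes across contrasts are
#' drawn from a bivariate normal with correlation `true_pcc` and marginal
#' standard deviation `sigma`. P-values are generated consistently with the
#' effect size (`p = 2 * pnorm(-|lfc| / sigma)`, uniform under the null).
#' Optionally, a protein table is coupled to the mRNA changes with an
#' attenuation factor plus independent noise, mimicking the damped,
#' delayed proteome response seen after stress.
#'
#' @param pair_truth Tibble with `mrna_id`, `asrna_id`, `true_pcc`.
#' @param n_contrasts Number of contrasts (>= 3; Pearson correlation is
#'   degenerate below that).
#' @param sigma Marginal standard deviation of the log2 fold changes.
#' @param protein If `TRUE`, also emit a protein fold-change table.
#' @param protein_attenuation Multiplier linking protein to mRNA changes.
#' @param protein_sigma Independent protein noise (sd, log2 units).
#' @param seed Integer seed.
#'
#' @return A list of long tibbles `mrna`, `asrna` (and `protein`), each with
#'   columns `feature_id`, `contrast_id`, `log2fc`, `pvalue`.
#' @export
simulate_expression <- function(pair_truth, n_contrasts = 10L, sigma = 1,
                                protein = FALSE, protein_attenuation = 0.5,
                                protein_sigma = 0.25, seed = 1L) {
  if (n_contrasts < 3) stop("n_contrasts must be >= 3 (PCC is degenerate below)")
  if (any(abs(pair_truth$true_pcc) > 1)) stop("true_pcc must be in [-1, 1]")
  n_pairs <- nrow(pair_truth)
  withr::with_seed(seed + 4000L, {
    rho <- pair_truth$true_pcc
    x <- matrix(stats::rnorm(n_pairs * n_contrasts, sd = sigma),
                nrow = n_pairs)
    z <- matrix(stats::rnorm(n_pairs * n_contrasts, sd = sigma),
                nrow = n_pairs)
    y <- rho * x + sqrt(1 - rho^2) * z
    if (protein) {
      prot <- protein_attenuation * x +
        matrix(stats::rnorm(n_pairs * n_contrasts, sd = protein_sigma),
               nrow = n_pairs)
    }
  })
  contrasts <- sprintf("contrast_%02d", seq_len(n_contrasts))
  long <- function(ids, m) {
    tibble::tibble(
      feature_id = rep(ids, times = n_contrasts),
      contrast_id = rep(contrasts, each = n_pairs),
      log2fc = as.vector(m),
      pvalue = 2 * stats::pnorm(-abs(as.vector(m)) / sigma)
    )
  }
  out <- list(mrna = long(pair_truth$mrna_id, x),
              asrna = long(pair_truth$asrna_id, y))
  if (protein) out$protein <- long(pair_truth$mrna_id, prot)
  out
}
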