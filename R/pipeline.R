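#' Pipeline configuration
#'
#' A flat list of every tunable threshold of the pipeline with the defaults
#' used throughout the package, so a full run is reproducible from its
#' config plus one seed.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # site detection
    alpha = 1e-9, min_reads = 10, group_gap = 5,
    min_score = 600, min_delta = 10, max_site_p = 0.05,
    upstream_window = 300, antisense_flank = 100,
    # transcript annotation
    tts_window = 400, min_aa = 10, max_aa = 49,
    min_tpm = 1, min_conditions = 1,
    # RIP-seq
    min_run = 10, lfc_threshold = 1, padj_peaks = 0.01, pseudocount = 1,
    gc_window = 50, gc_step = 25,
    # expression
    pcc_threshold = 0.5, de_lfc = 1, de_p = 0.05
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  }
  if (any(unlist(dots) <= 0 & names(dots) != "alpha")) {
    stop("all thresholds must be positive")
  }
  utils::modifyList(cfg, dots)
}

#' End-to-end synthetic demonstration run
#'
#' Generates a synthetic genome with planted ground truth, simulates every
#' input the pipeline consumes, runs all stages (site detection, TPS
#' calling, transcript annotation, RIP-seq peak calling, pair correlation,
#' direction agreement) and compares the calls with the planted truth.
#' Identical seeds give identical results.
#'
#' @param seed Integer seed controlling all randomness.
#' @param config A [pipeline_config()].
#' @param genome_length,n_tss,n_tps,n_peaks,n_pairs,n_transcripts Scale of
#'   the simulated study.
#' @param null_run If `TRUE`, nothing is planted: every stage should then
#'   return zero calls at default thresholds.
#' @param out_dir Optional directory: when given, tracks, annotations and
#'   result tables are also written to disk (bedgraph/GFF3/TSV).
#'
#' @return A list with the per-stage outputs (`sites`, `transcripts`,
#'   `peaks`, `pairs`, `integration`) and a `summary` tibble with one row
#'   per stage (sensitivity and precision against the planted truth).
#' @export
run_demo <- function(seed = 1L, config = pipeline_config(),
                     genome_length = 100000L, n_tss = 200L, n_tps = 100L,
                     n_peaks = 40L, n_pairs = 200L, n_transcripts = 25L,
                     null_run = FALSE, out_dir = NULL) {
  if (null_run) {
    n_tss <- n_tps <- n_peaks <- n_transcripts <- 0L
  }
  genome <- make_genome(length = genome_length,
                        n_genes = max(5L, genome_length %/% 1600L),
                        seed = seed)
  truth <- make_truth(
    genome = genome, n_tss = n_tss, n_tps = n_tps, n_peaks = n_peaks,
    n_pairs = n_pairs, n_transcripts = n_transcripts,
    true_pcc = if (n_pairs > 0) rep_len(c(-0.9, 0, 0.9), n_pairs) else numeric(),
    seed = seed
  )

  # --- stage 1: dRNA-seq site detection -------------------------------
  drna <- simulate_drna_tracks(truth, depth = 10, background_rate = 0.5,
                               seed = seed)
  sites <- list()
  for (st in c("plus", "minus")) {
    tss_calls <- call_sites(drna[[st]]$plus_tex, drna[[st]]$minus_tex,
                            min_reads = config$min_reads,
                            alpha = config$alpha,
                            group_gap = config$group_gap)
    tps_calls <- call_tps(drna[[st]]$plus_tex, drna[[st]]$minus_tex,
                          min_reads = config$min_reads,
                          alpha = config$alpha, group_gap = config$group_gap)
    sites[[st]] <- dplyr::bind_rows(tss_calls, tps_calls)
  }
  sites <- dplyr::bind_rows(sites) |>
    apply_site_filters(min_score = config$min_score,
                       min_delta = config$min_delta,
                       max_p = config$max_site_p) |>
    classify_tss(truth$genome$genes, genome_length = genome_length,
                 upstream_window = config$upstream_window,
                 antisense_flank = config$antisense_flank)
  site_stats <- dplyr::bind_rows(
    recovery_stats(sites[sites$site_type == "TSS", ],
                   truth$planted_tss, "TSS calling"),
    recovery_stats(sites[sites$site_type == "TPS", ],
                   truth$planted_tps, "TPS calling")
  )

  # --- stage 2: transcript annotation ---------------------------------
  tts_truth <- tibble::tibble(position = truth$planted_transcripts$tts,
                              strand = truth$planted_transcripts$strand)
  as_calls <- tibble::tibble(position = truth$planted_transcripts$tss,
                             strand = truth$planted_transcripts$strand,
                             tss_class = "aTSS")
  transcripts <- match_tts(as_calls, tts_truth, window = config$tts_window)
  if (nrow(transcripts) > 0) {
    transcripts <- transcripts |>
      assign_cognate_genes(truth$genome$genes) |>
      find_orfs(truth$genome$sequence, min_aa = config$min_aa,
                max_aa = config$max_aa)
  }
  tr_truth_key <- with(truth$planted_transcripts, paste(start, end, strand))
  tr_call_key <- if (nrow(transcripts) > 0) {
    with(transcripts, paste(start, end, strand))
  } else {
    character()
  }
  transcript_stats <- tibble::tibble(
    stage = "transcript annotation",
    n_true = length(tr_truth_key), n_called = length(tr_call_key),
    sensitivity = if (length(tr_truth_key) == 0) NA_real_ else
      mean(tr_truth_key %in% tr_call_key),
    precision = if (length(tr_call_key) == 0) NA_real_ else
      mean(tr_call_key %in% tr_truth_key)
  )

  # --- stage 3: RIP-seq peaks -----------------------------------------
  rip <- simulate_ripseq(truth, depth = 50, seed = seed)
  peaks <- purrr::map_dfr(c("plus", "minus"), function(st) {
    call_peaks(rip[[st]]$coip, rip[[st]]$mock, min_run = config$min_run,
               threshold = config$lfc_threshold,
               pseudocount = config$pseudocount,
               min_lfc = config$lfc_threshold,
               max_padj = config$padj_peaks)
  })
  peak_truth <- truth$planted_peaks
  peak_hit <- function(p_start, p_end, p_strand) {
    any(peak_truth$strand == p_strand & peak_truth$start < p_end &
          peak_truth$end > p_start)
  }
  peak_stats <- tibble::tibble(
    stage = "peak calling",
    n_true = nrow(peak_truth), n_called = nrow(peaks),
    sensitivity = if (nrow(peak_truth) == 0) NA_real_ else {
      mean(vapply(seq_len(nrow(peak_truth)), function(i) {
        any(peaks$strand == peak_truth$strand[i] &
              peaks$start < peak_truth$end[i] &
              peaks$end > peak_truth$start[i])
      }, logical(1)))
    },
    precision = if (nrow(peaks) == 0) NA_real_ else {
      mean(vapply(seq_len(nrow(peaks)), function(i) {
        peak_hit(peaks$start[i], peaks$end[i], peaks$strand[i])
      }, logical(1)))
    }
  )

  # --- stage 4: pair correlation --------------------------------------
  expr <- simulate_expression(truth$pair_truth, n_contrasts = 10,
                              seed = seed)
  pairs <- pair_pcc(truth$pair_truth, expr$mrna, expr$asrna,
                    pcc_threshold = config$pcc_threshold)
  strong <- abs(pairs$true_pcc) >= 0.9
  pair_stats <- tibble::tibble(
    stage = "pair correlation",
    n_true = nrow(pairs), n_called = sum(pairs$corr_class != "uncorrelated"),
    sensitivity = if (!any(strong)) NA_real_ else {
      mean(ifelse(pairs$true_pcc[strong] > 0,
                  pairs$corr_class[strong] == "positive",
                  pairs$corr_class[strong] == "negative"))
    },
    precision = NA_real_
  )

  # --- stage 5: integration -------------------------------------------
  direction <- direction_agreement(pairs, expr$mrna, expr$asrna,
                                   pcc_threshold = config$pcc_threshold)
  integration_stats <- tibble::tibble(
    stage = "integration",
    n_true = nrow(pairs), n_called = sum(direction$n_pairs),
    sensitivity = NA_real_, precision = NA_real_
  )

  summary <- dplyr::bind_rows(site_stats, transcript_stats, peak_stats,
                              pair_stats, integration_stats)
  result <- list(truth = truth, sites = sites, transcripts = transcripts,
                 peaks = peaks, pairs = pairs, integration = direction,
                 summary = summary, seed = seed, config = config)
  if (!is.null(out_dir)) write_demo_outputs(result, out_dir)
  result
}

recovery_stats <- function(calls, planted, stage) {
  key_true <- paste(planted$position, planted$strand)
  key_call <- paste(calls$position, calls$strand)
  tibble::tibble(
    stage = stage,
    n_true = nrow(planted), n_called = nrow(calls),
    sensitivity = if (nrow(planted) == 0) NA_real_ else
      mean(key_true %in% key_call),
    precision = if (nrow(calls) == 0) NA_real_ else
      mean(key_call %in% key_true)
  )
}

write_demo_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(result$truth$genome$sequence, file.path(out_dir, "genome.fa"))
  write_gff3(result$truth$genome$genes, file.path(out_dir, "genes.gff3"))
  write_truth(result$truth, file.path(out_dir, "truth"))
  readr::write_tsv(result$sites, file.path(out_dir, "site_calls.tsv"))
  if (nrow(result$sites) > 0) {
    bed <- dplyr::mutate(result$sites, start = .data$position,
                         end = .data$position + 1L,
                         id = paste0(.data$site_type, "_", .data$position))
    write_bed6(bed, file.path(out_dir, "site_calls.bed"))
  }
  readr::write_tsv(result$transcripts, file.path(out_dir, "transcripts.tsv"))
  readr::write_tsv(result$peaks, file.path(out_dir, "peaks.tsv"))
  readr::write_tsv(result$pairs, file.path(out_dir, "pairs.tsv"))
  readr::write_tsv(result$integration, file.path(out_dir, "direction_agreement.tsv"))
  readr::write_tsv(result$summary, file.path(out_dir, "summary.tsv"))
  invisible(out_dir)
}
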