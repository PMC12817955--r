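#' Match orphan/antisense TSSs to termination sites to build transcripts
#'
#' For each oTSS or aTSS, same-strand termination sites are searched within
#' a `window` nt stretch downstream of the TSS (strictly downstream, at most
#' `window` nt away, measured 5' to 3' on the call's strand). When several
#' fall in the window the nearest downstream TTS is chosen, giving the
#' shortest transcript consistent with both termini. Calls with no TTS in
#' the window yield no transcript. Antisense calls (`tss_class == "aTSS"`)
#' become asRNA candidates, orphan calls become sRNA candidates.
#'
#' @param tss_calls Classified, filtered site calls (only oTSS/aTSS rows are
#'   used).
#' @param tts Tibble with columns `position` (0-based), `strand`.
#' @param window Search window downstream of the TSS in nt.
#' @return A tibble of transcript candidates: `id`, `start`, `end` (0-based
#'   half-open), `strand`, `source_tss`, `matched_tts`, `category`,
#'   `expression_validated` (initialized `NA`).
#' @export
match_tts <- function(tss_calls, tts, window = 400) {
  check_strand(tts$strand)
  use <- tss_calls[tss_calls$tss_class %in% c("oTSS", "aTSS"), ]
  rows <- purrr::pmap_dfr(
    list(use$position, use$strand, use$tss_class),
    function(p, st, cls) {
      cand <- tts$position[tts$strand == st]
      dist <- if (st == "+") cand - p else p - cand
      cand <- cand[dist >= 1 & dist <= window]
      dist <- dist[dist >= 1 & dist <= window]
      if (length(cand) == 0) return(NULL)
      tts_pos <- cand[which.min(dist)]
      tibble::tibble(
        start = if (st == "+") p else tts_pos,
        end = (if (st == "+") tts_pos else p) + 1L,
        strand = st,
        source_tss = p,
        matched_tts = tts_pos,
        category = if (cls == "aTSS") "asRNA" else "sRNA"
      )
    }
  )
  if (nrow(rows) == 0) {
    return(tibble::tibble(id = character(), start = integer(),
                          end = integer(), strand = character(),
                          source_tss = integer(), matched_tts = integer(),
                          category = character(),
                          expression_validated = logical()))
  }
  rows <- dplyr::arrange(rows, .data$start)
  counts <- table(rows$category)
  rows$id <- NA_character_
  for (cat in names(counts)) {
    ix <- which(rows$category == cat)
    rows$id[ix] <- sprintf("%s_%03d", cat, seq_along(ix))
  }
  dplyr::relocate(
    dplyr::mutate(rows, expression_validated = NA), "id"
  )
}

#' Attach cognate genes to antisense transcript candidates
#'
#' An asRNA's cognate genes are the opposite-strand genes it overlaps by at
#' least 1 nt. A candidate overlapping several genes keeps all of them as a
#' comma-separated list in `cognate_gene_ids`.
#'
#' @param candidates Transcript-candidate tibble from [match_tts()].
#' @param annotation Annotation tibble with genes.
#' @return `candidates` with a `cognate_gene_ids` column (empty string for
#'   non-asRNA rows).
#' @export
assign_cognate_genes <- function(candidates, annotation) {
  genes <- annotation
  if ("type" %in% names(genes)) genes <- genes[genes$type == "gene", ]
  candidates$cognate_gene_ids <- vapply(seq_len(nrow(candidates)), function(i) {
    if (candidates$category[i] != "asRNA") return("")
    hit <- genes$strand != candidates$strand[i] &
      genes$start < candidates$end[i] & genes$end > candidates$start[i]
    paste(genes$id[hit], collapse = ",")
  }, character(1))
  candidates
}

#' Assess coding potential: find the longest ORF and flag small ORFs
#'
#' Scans the transcript sequence (strand-aware) for the longest open reading
#' frame that begins with one of `starts`, ends at an in-frame stop codon,
#' and lies fully inside the transcript. `aa_length` counts the codons
#' between start and stop codon (both excluded). Candidates whose longest
#' ORF encodes `min_aa`--`max_aa` amino acids are upgraded to category
#' `smORF`; everything else is left unchanged.
#'
#' @param candidates Transcript-candidate tibble.
#' @param genome Genome sequence.
#' @param min_aa,max_aa Inclusive bounds on the encoded protein length for
#'   the smORF upgrade (the conventional small-protein bound is < 50 aa).
#' @param starts Permitted start codons.
#' @return `candidates` with columns `orf_start`, `orf_end`
#'   (transcript-relative, 0-based half-open, `NA` if no ORF) and
#'   `aa_length`, with `category` upgraded where applicable.
#' @export
find_orfs <- function(candidates, genome, min_aa = 10, max_aa = 49,
                      starts = c("ATG", "GTG", "TTG")) {
  genome <- as_dnastring(genome)
  res <- purrr::pmap_dfr(
    list(candidates$start, candidates$end, candidates$strand),
    function(s, e, st) {
      seq <- extract_genome_seq(genome, s, e, st)
      orf <- longest_orf(seq, starts)
      tibble::tibble(orf_start = orf$start, orf_end = orf$end,
                     aa_length = orf$aa)
    }
  )
  out <- dplyr::bind_cols(candidates, res)
  upgrade <- !is.na(out$aa_length) & out$aa_length >= min_aa &
    out$aa_length <= max_aa
  out$category[upgrade] <- "smORF"
  out
}

# Longest ORF in a transcript-oriented sequence. Returns 0-based half-open
# coordinates within the sequence (start codon through stop codon) and the
# encoded length in amino acids (codons strictly between start and stop).
longest_orf <- function(seq, starts) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(seq)
  best <- list(start = NA_integer_, end = NA_integer_, aa = NA_integer_)
  if (n < 6) return(best)
  codon_at <- function(i) substr(seq, i, i + 2)  # 1-based
  for (frame in 0:2) {
    i <- 1 + frame
    open_at <- NA_integer_
    while (i + 2 <= n) {
      cod <- codon_at(i)
      if (is.na(open_at) && cod %in% starts) open_at <- i
      if (!is.na(open_at) && cod %in% stops) {
        aa <- (i - open_at) %/% 3 - 1L
        if (is.na(best$aa) || aa > best$aa) {
          best <- list(start = open_at - 1L, end = i + 2L, aa = aa)
        }
        open_at <- NA_integer_
      }
      i <- i + 3
    }
  }
  best
}

#' Validate candidate expression against a TPM matrix
#'
#' A candidate's expression is validated when its TPM reaches `min_tpm` in
#' at least `min_conditions` conditions; only validated candidates should
#' enter a final annotation. Candidates absent from the matrix are treated
#' as unvalidated, with a warning.
#'
#' @param candidates Transcript-candidate tibble.
#' @param tpm_matrix Tibble with a `feature_id` column and one numeric
#'   column per condition.
#' @param min_tpm TPM threshold.
#' @param min_conditions Minimum number of qualifying conditions.
#' @return `candidates` with `expression_validated` filled in.
#' @export
validate_expression <- function(candidates, tpm_matrix, min_tpm = 1,
                                min_conditions = 1) {
  cond_cols <- setdiff(names(tpm_matrix), "feature_id")
  idx <- match(candidates$id, tpm_matrix$feature_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " candidate(s) missing from the TPM matrix; ",
            "treated as unvalidated")
  }
  n_ok <- rep(0L, nrow(candidates))
  found <- !is.na(idx)
  if (any(found)) {
    m <- as.matrix(tpm_matrix[idx[found], cond_cols, drop = FALSE])
    n_ok[found] <- rowSums(m >= min_tpm)
  }
  candidates$expression_validated <- n_ok >= min_conditions
  candidates
}

#' Extract promoter regions upstream of transcript start sites
#'
#' Returns the `upstream` nt immediately 5' of each TSS on the transcript's
#' strand (reverse complemented for minus-strand transcripts), e.g. to look
#' for the archaeal TATA box typically centred 24-30 bp upstream of the TSS.
#' Sequences truncated at a genome edge are flagged.
#'
#' @param candidates Transcript-candidate tibble (uses `source_tss`), or any
#'   tibble with `source_tss`/`position` and `strand` columns.
#' @param genome Genome sequence.
#' @param upstream Length of the upstream window in nt (>= 1).
#' @return Tibble with `id` (if present), `tss`, `strand`, `sequence`,
#'   `truncated`. The sequence reads 5' to 3' towards the TSS, so offset
#'   `k` from its 3' end is `k + 1` nt upstream of the TSS.
#' @export
extract_promoters <- function(candidates, genome, upstream = 50) {
  stopifnot(upstream >= 1)
  genome <- as_dnastring(genome)
  L <- length(genome)
  pos <- if ("source_tss" %in% names(candidates)) {
    candidates$source_tss
  } else {
    candidates$position
  }
  out <- purrr::pmap_dfr(
    list(pos, candidates$strand),
    function(p, st) {
      if (st == "+") {
        lo <- max(0L, p - upstream); hi <- p
      } else {
        lo <- p + 1L; hi <- min(L, p + 1L + upstream)
      }
      tibble::tibble(
        tss = p, strand = st,
        sequence = if (hi > lo) extract_genome_seq(genome, lo, hi, st) else "",
        truncated = (hi - lo) < upstream
      )
    }
  )
  if ("id" %in% names(candidates)) {
    out <- dplyr::bind_cols(tibble::tibble(id = candidates$id), out)
  }
  out
}

#' IUPAC consensus motif
#'
#' @param name Motif label.
#' @param consensus IUPAC string (U is treated as T).
#' @param strandedness `"both"` to scan both strands, `"sense"` for the
#'   given orientation only.
#' @return An `iupac_motif` object.
#' @export
#' @examples
#' iupac_motif("Motif-1", "AACGACAAGAAACUAAAAC")
iupac_motif <- function(name, consensus, strandedness = c("both", "sense")) {
  strandedness <- match.arg(strandedness)
  consensus <- toupper(gsub("U", "T", toupper(consensus)))
  ok <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
  bad <- setdiff(strsplit(consensus, "")[[1]], ok)
  if (length(bad) > 0) {
    stop("invalid IUPAC letter(s) in consensus: ", paste(bad, collapse = ", "))
  }
  structure(list(name = name, consensus = consensus,
                 strandedness = strandedness), class = "iupac_motif")
}

#' Processing-site consensus motifs recurrently found at archaeal TPS flanks
#'
#' Four degenerate consensus motifs associated with RNA processing sites
#' (Motif-1 matches the CRISPR repeat context processed by Cas6 in type I-D
#' systems). Supplied ready-made for [scan_motif()].
#'
#' @return A named list of [iupac_motif()] objects.
#' @export
tps_motifs <- function() {
  list(
    motif1 = iupac_motif("Motif-1", "AACGACAAGAAACUAAAAC"),
    motif2 = iupac_motif("Motif-2", "HHNUUAHAHUURUDDVDNY"),
    motif3 = iupac_motif("Motif-3", "DNYHAAGGAYDHDG"),
    motif4 = iupac_motif("Motif-4", "DDNWDNHBYWRGGACWR")
  )
}

#' Scan sequences for a degenerate IUPAC motif
#'
#' Exact degenerate-letter matching via Biostrings; overlapping hits are
#' allowed, and with `strandedness = "both"` the reverse complement of each
#' sequence is scanned too.
#'
#' @param sequences Named character vector, `DNAStringSet`, or tibble with
#'   `id` and `sequence` columns.
#' @param motif An [iupac_motif()].
#' @return Tibble of hits: `id`, `offset` (0-based start on the given
#'   orientation of the sequence), `strand` (`"+"` for the sequence as
#'   given, `"-"` for its reverse complement).
#' @export
scan_motif <- function(sequences, motif) {
  stopifnot(inherits(motif, "iupac_motif"))
  if (is.data.frame(sequences)) {
    sequences <- stats::setNames(sequences$sequence, sequences$id)
  }
  if (is.character(sequences)) {
    if (is.null(names(sequences))) {
      names(sequences) <- sprintf("seq_%d", seq_along(sequences))
    }
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  pat <- Biostrings::DNAString(motif$consensus)
  scan_one <- function(subject, id, strand) {
    if (length(subject) < length(pat)) return(NULL)
    m <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
    if (length(m) == 0) return(NULL)
    tibble::tibble(id = id, offset = BiocGenerics::start(m) - 1L,
                   strand = strand)
  }
  hits <- purrr::imap_dfr(as.list(sequences), function(s, id) {
    out <- scan_one(s, id, "+")
    if (motif$strandedness == "both") {
      out <- dplyr::bind_rows(out,
        scan_one(Biostrings::reverseComplement(s), id, "-"))
    }
    out
  })
  if (nrow(hits) == 0) {
    hits <- tibble::tibble(id = character(), offset = integer(),
                           strand = character())
  }
  hits
}

#' Count motif hits per feature category
#'
#' Tallies [scan_motif()] hits by a category label (e.g. `"mRNA"` versus
#' `"ncRNA"`), mirroring the motif-occurrence tables reported for
#' processing-site flanks.
#'
#' @param hits Hit tibble from [scan_motif()].
#' @param categories Named character vector mapping sequence id to category.
#' @return Tibble with `category`, `n_hits`.
#' @export
count_motif_hits <- function(hits, categories) {
  tibble::tibble(category = unname(categories[hits$id])) |>
    dplyr::count(.data$category, name = "n_hits")
}

#' Count processing sites per transcript
#'
#' Counts same-strand TPS positions inside each annotated transcript
#' interval; transcripts without any TPS report 0, so the result is the full
#' per-transcript TPS distribution.
#'
#' @param tps_calls Site-call tibble with `position`, `strand`.
#' @param annotation Annotation tibble (all rows are counted against).
#' @return `annotation` ids with an `n_tps` column.
#' @export
count_tps_per_transcript <- function(tps_calls, annotation) {
  n <- vapply(seq_len(nrow(annotation)), function(i) {
    sum(tps_calls$strand == annotation$strand[i] &
          tps_calls$position >= annotation$start[i] &
          tps_calls$position < annotation$end[i])
  }, integer(1))
  tibble::tibble(id = annotation$id, n_tps = n)
}

#' Merge novel transcripts with a curated annotation, removing duplicates
#'
#' Features with at least `min_reciprocal_overlap` reciprocal overlap on the
#' same strand are collapsed, keeping the curated entry. The merged result
#' never contains two features with identical (start, end, strand).
#'
#' @param novel,curated Annotation tibbles.
#' @param min_reciprocal_overlap Reciprocal overlap fraction above which a
#'   novel feature is considered a duplicate of a curated one.
#' @return The merged annotation tibble.
#' @export
merge_annotations <- function(novel, curated, min_reciprocal_overlap = 0.9) {
  keep <- vapply(seq_len(nrow(novel)), function(i) {
    s <- novel$start[i]; e <- novel$end[i]; st <- novel$strand[i]
    ov <- pmax(0L, pmin(e, curated$end) - pmax(s, curated$start))
    rec <- curated$strand == st &
      ov / (e - s) >= min_reciprocal_overlap &
      ov / (curated$end - curated$start) >= min_reciprocal_overlap
    !any(rec)
  }, logical(1))
  out <- dplyr::bind_rows(curated, novel[keep, ])
  out[!duplicated(out[, c("start", "end", "strand")]), ]
}
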