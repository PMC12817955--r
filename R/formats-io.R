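#' Read a 4-column bedgraph file into a dense strand track
#'
#' Bedgraph intervals are 0-based half-open, matching the package's internal
#' convention, so no coordinate shift happens here. Values are kept as raw
#' counts; any normalization is performed downstream so that files stay
#' auditable.
#'
#' @param path Path to a 4-column bedgraph file (`chrom start end value`).
#' @param genome_length Genome length in nt; the returned track is dense over
#'   `[0, genome_length)`, with gaps filled with 0.
#' @param strand,library,replicate Track labels, see [strand_track()].
#'
#' @return A [strand_track()].
#' @export
read_bedgraph <- function(path, genome_length, strand = "+",
                          library = "lib", replicate = 1L) {
  genome_length <- as.integer(genome_length)
  stopifnot(genome_length >= 1)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines)]
  counts <- numeric(genome_length)
  if (length(lines) == 0L) {
    return(strand_track(counts, strand, library, replicate))
  }
  covered <- logical(genome_length)
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[[i]]))) next
    fields <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(fields) != 4L) {
      stop(sprintf("malformed bedgraph line %d in '%s': expected 4 fields, got %d",
                   i, path, length(fields)))
    }
    start <- suppressWarnings(as.integer(fields[2]))
    end <- suppressWarnings(as.integer(fields[3]))
    value <- suppressWarnings(as.numeric(fields[4]))
    if (anyNA(c(start, end, value))) {
      stop(sprintf("malformed bedgraph line %d in '%s': non-numeric field", i, path))
    }
    if (start < 0 || end > genome_length || start >= end) {
      stop(sprintf(
        "bedgraph line %d in '%s': interval [%d, %d) outside genome [0, %d) or empty",
        i, path, start, end, genome_length))
    }
    idx <- (start + 1L):end
    if (any(covered[idx])) {
      stop(sprintf("bedgraph line %d in '%s': overlapping intervals", i, path))
    }
    covered[idx] <- TRUE
    counts[idx] <- value
  }
  strand_track(counts, strand, library, replicate)
}

#' Write a strand track as a 4-column bedgraph file
#'
#' Runs of equal non-zero values are collapsed into single intervals;
#' zero runs are omitted. `read_bedgraph(write_bedgraph(x))` restores the
#' track exactly.
#'
#' @param track A [strand_track()].
#' @param path Output path.
#' @param chrom Chromosome name for column 1.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, chrom = "chr") {
  stopifnot(inherits(track, "strand_track"))
  r <- rle(track$counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  lines <- sprintf("%s\t%d\t%d\t%s", chrom, starts[keep], ends[keep],
                   format(r$values[keep], trim = TRUE, scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write genome annotations as GFF3
#'
#' The package-internal annotation is a tibble with 0-based half-open
#' coordinates; GFF3 is 1-based inclusive. These two functions are the single
#' choke point where the conversion happens. `read_gff3(write_gff3(x))`
#' restores `x` exactly (columns `id`, `type`, `start`, `end`, `strand`, plus
#' any character/numeric attribute columns).
#'
#' @param features Tibble with columns `id`, `type`, `start`, `end`,
#'   `strand`, and optionally further attribute columns.
#' @param path File path.
#' @param chrom Chromosome name.
#' @return `write_gff3()` returns `path` invisibly; `read_gff3()` returns the
#'   annotation tibble.
#' @export
write_gff3 <- function(features, path, chrom = "chr") {
  features <- validate_annotation(features)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand
  )
  GenomicRanges::mcols(gr)$type <- features$type
  GenomicRanges::mcols(gr)$ID <- features$id
  extra <- setdiff(names(features), c("id", "type", "start", "end", "strand"))
  for (col in extra) GenomicRanges::mcols(gr)[[col]] <- features[[col]]
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  df <- rtracklayer::readGFF(path)
  if (nrow(df) > 0 && any(df$end < df$start)) {
    stop("GFF3 parse error in '", path, "': end < start")
  }
  check_strand(as.character(df$strand))
  out <- tibble::tibble(
    id = as.character(df$ID),
    type = as.character(df$type),
    start = as.integer(df$start) - 1L,
    end = as.integer(df$end),
    strand = as.character(df$strand)
  )
  extra <- setdiff(names(df), c("seqid", "source", "type", "start", "end",
                                "score", "strand", "phase", "ID"))
  for (col in extra) {
    v <- df[[col]]
    if (is.list(v)) v <- vapply(v, function(x) paste(x, collapse = ","), character(1))
    out[[col]] <- utils::type.convert(as.character(v), as.is = TRUE)
  }
  validate_annotation(out)
}

validate_annotation <- function(features) {
  features <- tibble::as_tibble(features)
  required <- c("id", "type", "start", "end", "strand")
  missing <- setdiff(required, names(features))
  if (length(missing) > 0) {
    stop("annotation is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(features$id)) {
    stop("annotation ids must be unique (duplicated: ",
         paste(utils::head(unique(features$id[duplicated(features$id)]), 3),
               collapse = ", "), ")")
  }
  if (any(features$start < 0) || any(features$end <= features$start)) {
    stop("annotation coordinates must satisfy 0 <= start < end")
  }
  check_strand(features$strand)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features
}

#' Read a fold-change table
#'
#' Accepts externally produced differential-expression results (e.g. DESeq2
#' exports) as tab-separated text with columns `feature_id`, `log2fc`,
#' `pvalue`, and optionally `padj` and `contrast_id`. Records with missing
#' p-values are retained but excluded from significance calls downstream.
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble with columns `feature_id`, `log2fc`, `pvalue` (+ optional
#'   `padj`, `contrast_id`).
#' @export
read_fold_change_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        na = c("", "NA"), progress = FALSE)
  required <- c("feature_id", "log2fc", "pvalue")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("fold-change table '", path, "' is missing columns: ",
         paste(missing, collapse = ", "))
  }
  for (col in c("log2fc", "pvalue")) {
    v <- df[[col]]
    if (is.character(v)) {
      bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
      if (length(bad) > 0) {
        stop("fold-change table '", path, "': non-numeric ", col,
             " in row ", bad[1], " ('", v[bad[1]], "')")
      }
      df[[col]] <- as.numeric(v)
    }
  }
  if (anyNA(df$log2fc)) {
    stop("fold-change table '", path, "': non-numeric log2fc in row ",
         which(is.na(df$log2fc))[1])
  }
  key <- if ("contrast_id" %in% names(df)) {
    paste(df$feature_id, df$contrast_id)
  } else {
    df$feature_id
  }
  if (anyDuplicated(key)) {
    stop("fold-change table '", path, "': duplicated feature_id (",
         df$feature_id[duplicated(key)][1], ")")
  }
  tibble::as_tibble(df)
}

#' Write site or peak calls as BED6
#'
#' The score column is the conventional `round(-10 * log10(p))`, capped at
#' 1000, so more significant calls sort higher in genome browsers.
#'
#' @param df Tibble with columns `start`, `end` (0-based half-open),
#'   `strand`, `pvalue`, and optionally `id`.
#' @param path Output path.
#' @param chrom Chromosome name.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(df, path, chrom = "chr") {
  score <- ifelse(is.na(df$pvalue) | df$pvalue <= 0, 1000,
                  pmin(1000, round(-10 * log10(df$pvalue))))
  name <- if ("id" %in% names(df)) df$id else sprintf("site_%d", seq_len(nrow(df)))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   chrom, df$start, df$end, name, score, df$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write genome sequences (FASTA)
#'
#' Thin wrappers around Biostrings keeping a single entry point for sequence
#' I/O.
#'
#' @param path FASTA path.
#' @param genome A `DNAString`/`DNAStringSet` or plain character vector.
#' @param name Sequence name used when writing a single sequence.
#' @return `read_fasta()` returns a `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(genome, path, name = "chr") {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (inherits(genome, "DNAString")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    names(genome) <- if (length(genome) == 1) name else paste0(name, seq_along(genome))
  }
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a termination-site (TTS) table
#'
#' Term-seq derived 3' end positions as tab-separated text with columns
#' `position` (0-based) and `strand`.
#'
#' @param path TSV path.
#' @return Tibble with columns `position`, `strand`.
#' @export
read_tts_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("position", "strand") %in% names(df))) {
    stop("TTS table must have columns 'position' and 'strand'")
  }
  check_strand(df$strand)
  tibble::tibble(position = as.integer(df$position),
                 strand = as.character(df$strand))
}

# Strand-aware sequence extraction: 0-based half-open genomic interval,
# reverse-complemented for the minus strand. `genome` is a DNAString,
# DNAStringSet (first sequence used) or character scalar.
extract_genome_seq <- function(genome, start, end, strand) {
  genome <- as_dnastring(genome)
  s <- Biostrings::subseq(genome, start = start + 1L, end = end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

as_dnastring <- function(genome) {
  if (inherits(genome, "DNAString")) return(genome)
  if (inherits(genome, "DNAStringSet")) return(genome[[1]])
  if (is.character(genome) && length(genome) == 1) {
    return(Biostrings::DNAString(genome))
  }
  stop("`genome` must be a DNAString, DNAStringSet or single character string")
}
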