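fake_call <- function(position, strand = "+", tss_class = "oTSS") {
  tibble::tibble(position = as.integer(position), strand = strand,
                 tss_class = tss_class)
}

test_that("TTS matching picks the nearest downstream site in the window", {
  tts <- tibble::tibble(position = c(1200L, 1300L, 1450L), strand = "+")
  tr <- match_tts(fake_call(1000), tts[1, ], window = 400)
  expect_equal(tr$start, 1000L)
  expect_equal(tr$end, 1201L)
  expect_equal(tr$end - tr$start, 201L)
  expect_equal(tr$category, "sRNA")

  tts2 <- tibble::tibble(position = c(1100L, 1300L), strand = "+")
  expect_equal(match_tts(fake_call(1000), tts2)$matched_tts, 1100L)

  # 450 nt away: outside the window
  expect_equal(nrow(match_tts(fake_call(1000), tts[3, ])), 0)
  # upstream TTS is never a candidate
  expect_equal(nrow(match_tts(fake_call(1000),
                              tibble::tibble(position = 900L,
                                             strand = "+"))), 0)
})

test_that("TTS matching is strand-aware (downstream = decreasing on minus)", {
  tts <- tibble::tibble(position = c(800L, 1100L), strand = "-")
  tr <- match_tts(fake_call(1000, "-", "aTSS"), tts)
  expect_equal(tr$matched_tts, 800L)
  expect_equal(tr$start, 800L)
  expect_equal(tr$end, 1001L)
  expect_equal(tr$category, "asRNA")

  # same-strand requirement
  expect_equal(nrow(match_tts(fake_call(1000, "+"),
                              tibble::tibble(position = 1100L,
                                             strand = "-"))), 0)
})

test_that("every emitted transcript satisfies the window invariants", {
  withr::with_seed(13, {
    for (rep in 1:20) {
      calls <- fake_call(sample(500:5000, 10),
                         sample(c("+", "-"), 10, replace = TRUE),
                         sample(c("oTSS", "aTSS"), 10, replace = TRUE))
      tts <- tibble::tibble(position = sample(0:6000, 60),
                            strand = sample(c("+", "-"), 60, replace = TRUE))
      tr <- match_tts(calls, tts)
      if (nrow(tr) == 0) next
      expect_true(all(tr$end - tr$start <= 401))
      d <- ifelse(tr$strand == "+", tr$matched_tts - tr$source_tss,
                  tr$source_tss - tr$matched_tts)
      expect_true(all(d >= 1 & d <= 400))
    }
  })
})

test_that("ORF detection finds the longest ORF and applies the size gate", {
  aa30 <- paste(rep("GCT", 30), collapse = "")
  seq <- paste0("AAAA", "ATG", aa30, "TAA", "AA")
  genome <- Biostrings::DNAString(seq)
  cand <- tibble::tibble(id = "t1", start = 0L,
                         end = as.integer(nchar(seq)), strand = "+",
                         source_tss = 0L, matched_tts = 10L,
                         category = "sRNA", expression_validated = NA)
  out <- find_orfs(cand, genome)
  expect_equal(out$aa_length, 30L)
  expect_equal(out$category, "smORF")
  expect_equal(out$orf_start, 4L)
  expect_equal(out$orf_end, 4L + 3L + 90L + 3L)

  # no stop codon inside the transcript: no ORF
  seq2 <- paste0("AAAA", "ATG", aa30)
  cand2 <- dplyr::mutate(cand, end = as.integer(nchar(seq2)))
  out2 <- find_orfs(cand2, Biostrings::DNAString(seq2))
  expect_true(is.na(out2$aa_length))
  expect_equal(out2$category, "sRNA")

  # 60 aa (> 49): stays in its original category
  aa60 <- paste(rep("GCT", 60), collapse = "")
  seq3 <- paste0("ATG", aa60, "TAA")
  cand3 <- dplyr::mutate(cand, end = as.integer(nchar(seq3)))
  out3 <- find_orfs(cand3, Biostrings::DNAString(seq3))
  expect_equal(out3$aa_length, 60L)
  expect_equal(out3$category, "sRNA")
})

test_that("alternative start codons and minus-strand ORFs are handled", {
  aa12 <- paste(rep("GAA", 12), collapse = "")
  plus_orf <- paste0("GTG", aa12, "TAG")
  # embed the reverse complement so the ORF lives on the minus strand
  seq <- paste0("AAAA", revcomp_chr(plus_orf), "AAAA")
  cand <- tibble::tibble(id = "t1", start = 0L,
                         end = as.integer(nchar(seq)), strand = "-",
                         source_tss = 0L, matched_tts = 1L,
                         category = "asRNA", expression_validated = NA)
  out <- find_orfs(cand, Biostrings::DNAString(seq))
  expect_equal(out$aa_length, 12L)
  expect_equal(out$category, "smORF")
})

test_that("expression validation applies the TPM-by-condition rule", {
  cands <- tibble::tibble(id = c("t1", "t2", "t3"),
                          strand = "+", category = "sRNA")
  tpm <- tibble::tibble(feature_id = c("t1", "t2", "t3"),
                        c1 = c(0, 0, 1.5), c2 = c(0, 0, 0.2),
                        c3 = c(3.2, 0, 0.9))
  out <- validate_expression(cands, tpm)
  expect_equal(out$expression_validated, c(TRUE, FALSE, TRUE))

  out2 <- validate_expression(cands, tpm, min_conditions = 2)
  expect_equal(out2$expression_validated, c(FALSE, FALSE, FALSE))

  expect_warning(
    out3 <- validate_expression(
      tibble::tibble(id = "missing", strand = "+", category = "sRNA"), tpm),
    "missing")
  expect_false(out3$expression_validated)
})

test_that("promoter extraction returns the upstream window, strand-aware", {
  withr::with_seed(17, genome <- Biostrings::DNAString(random_seq(400)))
  cand <- tibble::tibble(id = "t1", source_tss = 200L, strand = "+")
  pr <- extract_promoters(cand, genome, upstream = 50)
  expect_equal(nchar(pr$sequence), 50)
  expect_equal(pr$sequence,
               as.character(Biostrings::subseq(genome, 151, 200)))

  pr_m <- extract_promoters(
    tibble::tibble(id = "t2", source_tss = 200L, strand = "-"),
    genome, upstream = 50)
  expect_equal(pr_m$sequence,
               revcomp_chr(as.character(Biostrings::subseq(genome, 202, 251))))

  pr_t <- extract_promoters(
    tibble::tibble(id = "t3", source_tss = 10L, strand = "+"), genome)
  expect_true(pr_t$truncated)
  expect_equal(nchar(pr_t$sequence), 10)
})

test_that("a planted TATA box shows up at the expected promoter offset", {
  # plant TATAAA so its first base sits 27 nt upstream of the TSS
  withr::with_seed(19, {
    n <- 150
    seqs <- vapply(seq_len(n), function(i) {
      s <- strsplit(random_seq(50), "")[[1]]
      s[(50 - 27 + 1):(50 - 27 + 6)] <- c("T", "A", "T", "A", "A", "A")
      paste(s, collapse = "")
    }, character(1))
  })
  # base frequency at each offset from the 3' end of the extract
  at_offset <- function(off) {
    mean(substr(seqs, 50 - off + 1, 50 - off + 1) == "T")
  }
  expect_equal(at_offset(27), 1)
  expect_lt(at_offset(40), 0.6)
})

test_that("IUPAC motif scanning matches a brute-force sliding comparison", {
  motifs <- c("ACGT", "HAY", "DNYHAAGGAYDHDG", "NNWWS", "RYKM")
  withr::with_seed(23, {
    for (rep in 1:40) {
      seq <- random_seq(sample(20:120, 1))
      cons <- sample(motifs, 1)
      m <- iupac_motif("m", cons, strandedness = "sense")
      got <- scan_motif(c(s1 = seq), m)
      expect_equal(got$offset, brute_iupac_match(seq, cons))
    }
  })
})

test_that("motif scanning handles the degenerate-letter definition and U", {
  m <- iupac_motif("m", "H")
  # H = A/C/T never matches G on the given strand; on the reverse
  # complement G reads as C, which H does match
  expect_equal(nrow(scan_motif(c(a = "G"),
                               iupac_motif("m", "H", "sense"))), 0)
  expect_equal(scan_motif(c(a = "G"), m)$strand, "-")
  expect_equal(nrow(scan_motif(c(a = "A"),
                               iupac_motif("m", "H", "sense"))), 1)
  # U in the consensus is treated as T
  expect_equal(scan_motif(c(a = "CTG"),
                          iupac_motif("m", "U", "sense"))$offset, 1L)
  expect_error(iupac_motif("bad", "AXC"), "IUPAC")
})

test_that("a processing-site consensus is found exactly where constructed", {
  m1 <- tps_motifs()$motif1
  withr::with_seed(29, seq <- paste0(random_seq(30),
                                     "AACGACAAGAAACTAAAAC", random_seq(30)))
  hits <- scan_motif(c(s = seq), m1)
  expect_equal(nrow(hits[hits$strand == "+", ]), 1)
  expect_equal(hits$offset[hits$strand == "+"], 30L)

  # total hit count is strand-symmetric
  hits_rc <- scan_motif(c(s = revcomp_chr(seq)), m1)
  expect_equal(nrow(hits), nrow(hits_rc))
})

test_that("TPS-per-transcript counting is interval- and strand-exact", {
  ann <- tibble::tibble(id = c("t1", "t2"), type = "gene",
                        start = c(100L, 500L), end = c(200L, 600L),
                        strand = c("+", "-"))
  tps <- tibble::tibble(position = c(100L, 150L, 199L, 200L, 550L),
                        strand = c("+", "+", "+", "+", "+"))
  out <- count_tps_per_transcript(tps, ann)
  expect_equal(out$n_tps, c(3L, 0L))  # 200 is outside [100,200); 550 wrong strand
})

test_that("annotation merging collapses reciprocal duplicates, keeping curated", {
  curated <- tibble::tibble(id = "known_1", type = "sRNA", start = 100L,
                            end = 300L, strand = "+")
  novel <- tibble::tibble(
    id = c("new_1", "new_2"), type = "sRNA",
    start = c(102L, 1000L), end = c(298L, 1200L), strand = "+")
  out <- merge_annotations(novel, curated)
  expect_equal(sort(out$id), c("known_1", "new_2"))
  key <- paste(out$start, out$end, out$strand)
  expect_false(any(duplicated(key)))
})
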