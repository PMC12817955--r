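# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with R/.

# O(n^2) transitive-closure grouper: candidates belong to one group when
# connected by steps of <= gap nt. Returns representative positions.
brute_group <- function(pos, counts, strand, gap) {
  n <- length(pos)
  if (n == 0) return(integer())
  adj <- abs(outer(pos, pos, "-")) <= gap
  group <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && group[j] != group[i]) {
        g <- min(group[i], group[j])
        group[group == group[i] | group == group[j]] <- g
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  reps <- sapply(unique(group), function(g) {
    ix <- which(group == g)
    best <- ix[counts[ix] == max(counts[ix])]
    if (strand == "+") min(pos[best]) else max(pos[best])
  })
  sort(reps)
}

# Regex-free sliding IUPAC comparison (single orientation).
iupac_table <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

brute_iupac_match <- function(seq, consensus) {
  consensus <- gsub("U", "T", toupper(consensus))
  s <- strsplit(toupper(seq), "")[[1]]
  m <- strsplit(consensus, "")[[1]]
  k <- length(m)
  hits <- integer()
  if (length(s) < k) return(hits)
  for (off in 0:(length(s) - k)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!(s[off + j] %in% iupac_table[[m[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

revcomp_chr <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(toupper(seq), "")[[1]]]), collapse = "")
}

# Position-by-position run scanner for threshold runs.
brute_runs <- function(x, min_run, threshold) {
  above <- x >= threshold
  runs <- list()
  i <- 1
  while (i <= length(x)) {
    if (above[i]) {
      j <- i
      while (j <= length(x) && above[j]) j <- j + 1
      # store 0-based inclusive ends
      if (j - i >= min_run) runs[[length(runs) + 1]] <- c(i - 1, j - 2)
      i <- j
    } else {
      i <- i + 1
    }
  }
  if (length(runs) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  m <- do.call(rbind, runs)
  data.frame(start = m[, 1], end = m[, 2])
}

# Pearson correlation from first principles.
brute_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
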