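test_that("TPM follows the closed form and always sums to 1e6", {
  expect_equal(tpm(c(10, 10), c(100, 100)), c(5e5, 5e5))
  expect_equal(tpm(c(10, 10), c(100, 200)),
               c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  withr::with_seed(73, {
    for (i in 1:10) {
      v <- rpois(50, 40)
      l <- sample(100:2000, 50)
      expect_equal(sum(tpm(v, l)), 1e6, tolerance = 1e-6)
    }
  })
  expect_equal(tpm(c(0, 0), c(100, 200)), c(0, 0))
  m <- tpm(cbind(a = c(10, 10), b = c(5, 0)), c(100, 100))
  expect_equal(colSums(m), c(a = 1e6, b = 1e6))
  expect_error(tpm(c(1, 1), c(0, 100)), "> 0")
})

test_that("size factors recover a known depth ratio (median of ratios)", {
  withr::with_seed(79, counts <- matrix(rpois(400, 100), ncol = 2))
  rownames(counts) <- sprintf("g%03d", 1:200)
  doubled <- cbind(counts, counts * 2)
  sf <- size_factors(doubled)
  expect_equal(unname(sf[3] / sf[1]), 2, tolerance = 1e-9)
  expect_equal(unname(sf[4] / sf[2]), 2, tolerance = 1e-9)
})

test_that("the DE stand-in is null-calibrated and recovers planted changes", {
  withr::with_seed(83, {
    a <- matrix(rpois(2000 * 3, 200), ncol = 3)
    b <- matrix(rpois(2000 * 3, 200), ncol = 3)
    rownames(a) <- rownames(b) <- sprintf("g%04d", 1:2000)
    null_res <- de_stand_in(a, b)
    # type-I error at nominal 0.05
    rate <- mean(null_res$pvalue < 0.05, na.rm = TRUE)
    expect_lt(abs(rate - 0.05), 0.02)
    # the |lfc| >= 1 gate removes essentially everything under the null
    expect_lte(sum(null_res$significant), 2)

    # planted 4-fold change
    b2 <- b
    b2[1:50, ] <- matrix(rpois(50 * 3, 800), ncol = 3)
    res <- de_stand_in(a, b2)
    expect_true(all(abs(res$log2fc[1:50] - 2) <= 0.3))
    expect_true(all(res$significant[1:50]))
  })
})

test_that("DE stand-in validates its inputs", {
  m <- matrix(rpois(20, 10), ncol = 2,
              dimnames = list(sprintf("g%d", 1:10), NULL))
  expect_error(de_stand_in(m[, 1, drop = FALSE], m), ">= 2 replicates")
  m2 <- m; rownames(m2)[1] <- "other"
  expect_error(de_stand_in(m, m2), "differ")
})

test_that("antisense pairs require opposite-strand overlap of >= 1 nt", {
  ann <- tibble::tibble(
    id = c("g1", "g2", "as1", "as2", "as3"),
    type = c("gene", "gene", "asRNA", "asRNA", "asRNA"),
    start = c(100L, 300L, 150L, 280L, 150L),
    end = c(250L, 500L, 200L, 350L, 200L),
    strand = c("+", "+", "-", "-", "+")
  )
  pairs <- build_pairs(ann)
  # as1 inside g1 (opposite strand); as2 spans g1/g2 boundary -> g2 only
  # (no overlap with g1: 280 >= 250); as3 is same-strand -> no pair
  expect_equal(nrow(pairs), 2)
  expect_equal(sort(pairs$asrna_id), c("as1", "as2"))
  as_span <- tibble::tibble(
    id = c("g1", "g2", "asX"), type = c("gene", "gene", "asRNA"),
    start = c(100L, 240L, 150L), end = c(240L, 400L, 260L),
    strand = c("+", "+", "-"))
  expect_equal(nrow(build_pairs(as_span)), 2)  # one asRNA, two cognate genes
})

test_that("pair PCC matches hand arithmetic and brute force", {
  lfc <- function(id, v) {
    tibble::tibble(feature_id = id,
                   contrast_id = sprintf("c%d", seq_along(v)), log2fc = v)
  }
  pr <- tibble::tibble(mrna_id = "m", asrna_id = "a")
  same <- pair_pcc(pr, lfc("m", c(1, -2, 3, 0.5)), lfc("a", c(1, -2, 3, 0.5)))
  expect_equal(same$pcc, 1)
  expect_equal(same$corr_class, "positive")

  anti <- pair_pcc(pr, lfc("m", c(1, 2, 3)), lfc("a", c(-1, -2, -3)))
  expect_equal(anti$pcc, -1)
  expect_equal(anti$corr_class, "negative")

  hand <- pair_pcc(pr, lfc("m", c(1, 2, 3, 4)), lfc("a", c(1, 2, 3, 5)))
  expect_equal(hand$pcc, 0.982707629, tolerance = 1e-6)

  withr::with_seed(89, {
    for (i in 1:200) {
      n <- sample(3:12, 1)
      x <- rnorm(n); y <- rnorm(n)
      got <- pair_pcc(pr, lfc("m", x), lfc("a", y))$pcc
      expect_lt(abs(got - brute_pearson(x, y)), 1e-12)
    }
  })
})

test_that("degenerate PCC inputs yield missing values, not zero", {
  lfc <- function(id, v) {
    tibble::tibble(feature_id = id,
                   contrast_id = sprintf("c%d", seq_along(v)), log2fc = v)
  }
  pr <- tibble::tibble(mrna_id = "m", asrna_id = "a")
  flat <- pair_pcc(pr, lfc("m", c(1, 1, 1)), lfc("a", c(1, 2, 3)))
  expect_true(is.na(flat$pcc))
  expect_equal(flat$corr_class, "uncorrelated")

  few <- pair_pcc(pr, lfc("m", c(1, 2)), lfc("a", c(1, 2)))
  expect_true(is.na(few$pcc))
  expect_equal(few$n_contrasts_used, 2L)
})

test_that("direction agreement applies the sign rule and excludes zeros", {
  pairs <- tibble::tibble(mrna_id = c("m1", "m2", "m3"),
                          asrna_id = c("a1", "a2", "a3"),
                          pcc = c(0.9, -0.8, 0.2))
  one_tp <- function(ids, v) {
    tibble::tibble(feature_id = ids, timepoint = "t15", log2fc = v)
  }
  # m3/a3 filtered out by |pcc| < 0.5; one same, one opposite
  out <- direction_agreement(pairs,
                             one_tp(c("m1", "m2", "m3"), c(1.2, 0.5, 2)),
                             one_tp(c("a1", "a2", "a3"), c(-0.8, 0.5, 2)))
  expect_equal(out$n_pairs, 2L)
  expect_equal(out$pct_same, 50)
  expect_equal(out$pct_opposite, 50)
  expect_equal(out$pct_same + out$pct_opposite, 100)

  # zero fold change is excluded from the denominator
  out0 <- direction_agreement(pairs,
                              one_tp(c("m1", "m2"), c(1, 0)),
                              one_tp(c("a1", "a2"), c(1, 1)))
  expect_equal(out0$n_pairs, 1L)
  expect_equal(out0$pct_same, 100)

  expect_error(direction_agreement(pairs,
                                   one_tp(c("m1", "m2"), c(0, 0)),
                                   one_tp(c("a1", "a2"), c(1, 1))),
               "no pairs")
})

test_that("percentages sum to 100 exactly for random direction inputs", {
  withr::with_seed(97, {
    for (i in 1:20) {
      n <- sample(2:50, 1)
      pairs <- tibble::tibble(mrna_id = sprintf("m%d", 1:n),
                              asrna_id = sprintf("a%d", 1:n),
                              pcc = runif(n, -1, 1))
      tp <- tibble::tibble(feature_id = c(pairs$mrna_id, pairs$asrna_id),
                           timepoint = "t", log2fc = rnorm(2 * n))
      out <- try(direction_agreement(pairs, tp, tp), silent = TRUE)
      if (inherits(out, "try-error")) next  # no pair passed the filter
      expect_identical(out$pct_same + out$pct_opposite, 100)
    }
  })
})

test_that("planted anticorrelated pairs move in opposite directions", {
  pt <- tibble::tibble(mrna_id = sprintf("m%03d", 1:500),
                       asrna_id = sprintf("a%03d", 1:500),
                       true_pcc = -0.9)
  ex <- simulate_expression(pt, n_contrasts = 10, seed = 3)
  pairs <- pair_pcc(pt, ex$mrna, ex$asrna)
  out <- direction_agreement(pairs, ex$mrna, ex$asrna)
  expect_true(all(out$pct_opposite >= 80))
})

test_that("protein integration classifies and tabulates jointly", {
  pairs <- tibble::tibble(mrna_id = c("m1", "m2"), asrna_id = c("a1", "a2"))
  tbl <- function(ids, lfc, p) {
    tibble::tibble(feature_id = ids, log2fc = lfc, pvalue = p)
  }
  res <- protein_integration(
    pairs,
    lfc_asrna = tbl(c("a1", "a2"), c(2, 0.2), c(0.01, 0.5)),
    lfc_mrna = tbl(c("m1", "m2"), c(0.1, 0.3), c(0.5, 0.5)),
    lfc_protein = tbl(c("m1", "m2"), c(-1.5, 0), c(0.01, 0.9))
  )
  expect_equal(res$categories$joint_category[1], "asRNA-up/protein-down")
  s <- res$summary
  expect_equal(s$pct[s$molecule == "asRNA" & s$direction == "up"], 50)
  # percentages per molecule partition to 100
  sums <- tapply(s$pct, s$molecule, sum)
  expect_true(all(abs(sums - 100) < 1e-9))

  # all below thresholds -> everything unchanged
  res0 <- protein_integration(
    pairs,
    tbl(c("a1", "a2"), c(0.5, -0.5), c(0.2, 0.2)),
    tbl(c("m1", "m2"), c(0.5, -0.5), c(0.2, 0.2)),
    tbl(c("m1", "m2"), c(0.5, -0.5), c(0.2, 0.2)))
  expect_true(all(res0$summary$pct[res0$summary$direction == "unchanged"] == 100))

  # missing protein rows are excluded and counted
  res_m <- protein_integration(
    pairs,
    tbl(c("a1", "a2"), c(2, 2), c(0.01, 0.01)),
    tbl(c("m1", "m2"), c(0, 0), c(0.5, 0.5)),
    tbl("m1", -1.5, 0.01))
  expect_equal(res_m$n_excluded, 1L)
  expect_equal(nrow(res_m$categories), 1)
})

test_that("group trajectories match hand arithmetic on a toy table", {
  lfc <- tibble::tibble(
    feature_id = c("t1", "t2", "t3", "t4"),
    timepoint = "t15",
    log2fc = c(-1, -2, 1, 3))
  suppressWarnings(
    out <- smap_group_trajectories(c("t1", "t2"), character(), lfc))
  bound <- out[out$group == "smap1_only", ]
  expect_equal(bound$mean_log2fc, -1.5)
  expect_equal(bound$se, sd(c(-1, -2)) / sqrt(2))
  unbound <- out[out$group == "unbound", ]
  expect_equal(unbound$mean_log2fc, 2)
})

test_that("a planted bound-group shift is detected against unbound", {
  withr::with_seed(101, {
    ids <- sprintf("t%03d", 1:400)
    lfc <- tibble::tibble(
      feature_id = ids, timepoint = "t15",
      log2fc = c(rnorm(200, -1, 0.8), rnorm(200, 0, 0.8)))
  })
  suppressWarnings(
    out <- smap_group_trajectories(ids[1:200], character(), lfc))
  expect_lt(out$padj_vs_unbound[out$group == "smap1_only"], 0.005)
  expect_equal(out$signif[out$group == "smap1_only"], "***")

  # all transcripts unbound: only the unbound trajectory remains
  expect_warning(
    out0 <- smap_group_trajectories(character(), character(), lfc),
    "empty")
  expect_equal(unique(out0$group), "unbound")
})

test_that("DE tidiers return the per-feature table and model summary", {
  withr::with_seed(103, {
    a <- matrix(rpois(300, 100), ncol = 3,
                dimnames = list(sprintf("g%d", 1:100), NULL))
    b <- a; b[1:5, ] <- b[1:5, ] * 8
  })
  res <- de_stand_in(a, b)
  td <- tidy(res)
  expect_false(inherits(td, "de_result"))
  expect_equal(nrow(td), 100)
  gl <- glance(res)
  expect_equal(gl$n_features, 100L)
  expect_gte(gl$n_significant, 5L)
})
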