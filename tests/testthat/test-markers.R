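test_that("exact rank-sum p matches hand-derived values", {
  out <- rank_sum_test(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(out$p_value, 0.1)          # 2 extreme splits of C(6,3) = 20
  expect_equal(out$statistic, 6)

  same <- rank_sum_test(c(2, 4, 9), c(2, 4, 9), mode = "exact")
  expect_equal(same$p_value, 1)

  expect_error(rank_sum_test(numeric(), 1:3), "non-empty")
})

test_that("exact mode equals brute-force enumeration for small samples", {
  set.seed(20)
  for (n1 in c(1L, 2L, 4L, 8L)) for (n2 in c(1L, 3L, 8L)) {
    x <- sample(1:5, n1, replace = TRUE)   # heavy ties on purpose
    y <- sample(1:5, n2, replace = TRUE)
    expect_equal(rank_sum_test(x, y, "exact")$p_value,
                 ranksum_enumerate(x, y),
                 info = paste(n1, n2, "ties"))
    xc <- rnorm(n1); yc <- rnorm(n2)       # continuous, no ties
    expect_equal(rank_sum_test(xc, yc, "exact")$p_value,
                 ranksum_enumerate(xc, yc),
                 info = paste(n1, n2, "continuous"))
    # stats::wilcox.test agrees in the untied case
    pw <- suppressWarnings(stats::wilcox.test(xc, yc, exact = TRUE)$p.value)
    expect_equal(rank_sum_test(xc, yc, "exact")$p_value, pw)
  }
})

test_that("normal approximation tracks the exact null at moderate n", {
  set.seed(21)
  for (rep in 1:4) {
    x <- rnorm(30); y <- rnorm(30, 0.3)
    # exact null via the internal convolution (enumeration-equivalent)
    pe <- rank_sum_exact_p(rank(c(x, y)), 30L)
    pn <- rank_sum_test(x, y, "normal")$p_value
    expect_lt(abs(pn - pe), 0.005)
  }
})

test_that("exact mode refuses oversized enumerations", {
  expect_error(rank_sum_test(rnorm(30), rnorm(30), "exact"),
               class = "chromastrat_use_normal")
})

test_that("marker criteria carry the three-threshold defaults", {
  crit <- marker_criteria()
  expect_equal(crit$p_threshold, 1e-6)
  expect_equal(crit$min_fraction, 0.20)
  expect_equal(crit$min_fold, 2.0)
  expect_error(marker_criteria(min_fraction = 0), "min_fraction")
})

test_that("select_markers enforces all three criteria jointly", {
  set.seed(22)
  n_a <- 50L; n_b <- 150L
  lab <- rep(c(1L, 2L), c(n_a, n_b))
  norm <- rbind(
    strong = c(rpois(n_a, 10) + 1, rpois(n_b, 1)),        # all criteria pass
    sparse = c(ifelse(runif(n_a) < 0.1, 50, 0), rpois(n_b, 0.2)),  # <20% cells
    flat   = rpois(n_a + n_b, 4)                          # no signal
  )
  colnames(norm) <- paste0("c", seq_len(n_a + n_b))
  mk <- select_markers(norm, lab)
  expect_true("strong" %in% mk$gene[mk$cluster == 1L])
  expect_false("sparse" %in% mk$gene[mk$cluster == 1L])
  expect_false("flat" %in% mk$gene)
  rec <- mk[mk$gene == "strong" & mk$cluster == 1L, ]
  # recompute the three criteria directly
  expect_lt(rec$p_value,
            suppressWarnings(stats::wilcox.test(
              norm["strong", lab == 1], norm["strong", lab == 2]))$p.value * 10)
  expect_equal(rec$fraction_in, mean(norm["strong", lab == 1] > 0))
  expect_equal(rec$fold,
               (mean(norm["strong", lab == 1]) + 1e-9) /
               (mean(norm["strong", lab == 2]) + 1e-9))
  expect_equal(rec$log2fc, log2(rec$fold), tolerance = 1e-12)
})

test_that("noise labels and undersized clusters are excluded", {
  set.seed(23)
  norm <- matrix(rpois(300, 3), 3, 100,
                 dimnames = list(paste0("g", 1:3), paste0("c", 1:100)))
  lab <- c(rep(1L, 48), rep(2L, 48), rep(-1L, 2), 3L, 3L)
  expect_warning(out <- marker_stats(norm, lab[1:100]), "skipped")
  expect_setequal(unique(out$cluster), c(1L, 2L))
  expect_error(marker_stats(norm, rep(1L, 100)), "at least 2")
})

test_that("log2fc matrix matches marker records and planted effects", {
  set.seed(24)
  # planted 2^1.5 effect, recovered within 0.2 at n = 500
  n <- 500L
  lab <- rep(c(1L, 2L), c(150L, 350L))
  base <- 3
  x <- rbind(
    hit  = rpois(n, base * ifelse(lab == 1L, 2^1.5, 1)),
    same = rpois(n, base)
  )
  colnames(x) <- paste0("c", 1:n)
  m <- log2fc_matrix(x, lab, sort_rows = FALSE)
  expect_equal(m["hit", "1"], 1.5, tolerance = 0.2)
  expect_equal(m["same", "1"], 0, tolerance = 0.25)
  # identical means everywhere -> zero row
  flat <- rbind(z = rep(2, 100))
  colnames(flat) <- paste0("c", 1:100)
  mf <- log2fc_matrix(flat, rep(c(1L, 2L), 50), sort_rows = FALSE)
  expect_equal(unname(mf["z", ]), c(0, 0))
  # shared computation with marker stats
  st <- marker_stats(x, lab, min_cluster_size = 1L)
  expect_equal(m["hit", "1"],
               st$log2fc[st$gene == "hit" & st$cluster == 1L])
  expect_error(log2fc_matrix(x, lab, genes = "absent"), "absent")
})

test_that("marker tests control type-I error at the stated threshold", {
  # label permutation on null data; >= 1e5 (gene, cluster) tests
  set.seed(25)
  G <- 1000L; n <- 1000L
  norm <- matrix(rpois(G * n, 2), G, n,
                 dimnames = list(paste0("g", 1:G), paste0("c", 1:n)))
  n_small <- 0L; n_tests <- 0L
  for (perm in 1:25) {
    lab <- sample(rep(1:4, length.out = n))
    st <- marker_stats(norm, lab)
    n_small <- n_small + sum(st$p_value < 1e-6)
    n_tests <- n_tests + nrow(st)
  }
  expect_gte(n_tests, 1e5)
  expect_lte(n_small / n_tests, 1e-5)
})
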