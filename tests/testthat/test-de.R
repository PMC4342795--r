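# Audic-Claverie exact statistic, BH FDR, pairwise DE calls and the
# union DEG set.

test_that("ac_probability matches closed forms and the oracle", {
  # equal library sizes: p(y|x) = C(x+y, x) / 2^(x+y+1)
  expect_equal(ac_probability(0, 0, 1e5, 1e5), 0.5)
  expect_equal(ac_probability(1, 1, 1e5, 1e5), 0.25)
  expect_equal(ac_probability(5, 0, 1e5, 1e5), 1 / 64)

  # unequal sizes against the direct (non-log) formula
  for (case in list(c(3, 7, 1e5, 2e5), c(0, 4, 4.3e6, 4.7e6),
                    c(12, 2, 2e4, 1e4))) {
    expect_equal(ac_probability(case[1], case[2], case[3], case[4]),
                 ac_oracle(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-12)
  }

  # y | x is NegBinom(x + 1, N1 / (N1 + N2)): independent distributional
  # route
  expect_equal(ac_probability(6, 0:40, 1e5, 3e5),
               dnbinom(0:40, size = 7, prob = 0.25), tolerance = 1e-12)

  expect_error(ac_probability(-1, 0, 1, 1), "non-negative")
  expect_error(ac_probability(0, 0, 0, 1), "positive")
})

test_that("ac_probability sums to one over y", {
  for (x in c(0, 1, 5, 20)) {
    total <- sum(ac_probability(x, 0:2000, 1e5, 1e5))
    expect_lt(abs(total - 1), 1e-9)
  }
})

test_that("ac_two_sided_p matches tail summation, symmetry and scale", {
  expect_equal(ac_two_sided_p(5, 0, 1e5, 1e5), 0.03125)
  # x = y with equal totals: symmetric distribution, p capped at 1
  for (x in c(0, 3, 10, 20)) {
    expect_equal(ac_two_sided_p(x, x, 1e5, 1e5), 1)
  }
  # large imbalance: vanishing p (closed form 2^-49 for x=0, y=50)
  expect_lt(ac_two_sided_p(0, 50, 1e5, 1e5), 1e-10)
  expect_equal(ac_two_sided_p(0, 50, 1e5, 1e5), 2^-49, tolerance = 1e-9)

  set.seed(17)
  for (i in 1:25) {
    x <- rpois(1, 20); y <- rpois(1, 20)
    N1 <- sample(c(1e4, 1e5), 1); N2 <- sample(c(1e4, 2e5), 1)
    expect_equal(ac_two_sided_p(x, y, N1, N2),
                 ac_two_sided_oracle(x, y, N1, N2, y_max = 2000L),
                 tolerance = 1e-10)
    # swapping the conditioning count changes the discrete tails by at
    # most the boundary point mass: near-symmetry within a factor of 2
    p_xy <- ac_two_sided_p(x, y, 1e5, 1e5)
    p_yx <- ac_two_sided_p(y, x, 1e5, 1e5)
    expect_lte(abs(log(p_xy) - log(p_yx)), log(2) + 1e-12)
  }

  # doubling N2 shifts the conditional mean of y to (x+1) * N2/N1 - ...
  # check E[y | x] against brute-force expectation
  x <- 10
  ys <- 0:5000
  m <- sum(ys * ac_probability(x, ys, 1e5, 2e5))
  m_oracle <- sum(ys * ac_oracle(x, ys, 1e5, 2e5))
  expect_equal(m, m_oracle, tolerance = 1e-9)
  expect_equal(m, (x + 1) * 2, tolerance = 1e-6)  # NB mean: size*(1-p)/p
})

test_that("bh_fdr is a step-up BH matching the loop oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.4), 0.4)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "in \\[0, 1\\]")

  set.seed(23)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    adj <- bh_fdr(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-14)
    expect_equal(adj, p.adjust(p, method = "BH"), tolerance = 1e-14)
    # sorted input gives non-decreasing output
    expect_true(all(diff(bh_fdr(sort(p))) >= 0))
    expect_true(all(adj >= p - 1e-15))
  }
  p <- runif(100)
  expect_equal(bh_fdr(p, method = "BY"), p.adjust(p, method = "BY"),
               tolerance = 1e-14)
})

test_that("call_pairwise applies the three filters and exclusions", {
  counts <- cbind(a = c(0L, 2L, 50L, 100L, 40L),
                  b = c(0L, 9L, 50L, 0L, 400L))
  rownames(counts) <- paste0("g", 1:5)
  expr <- make_expr(counts, clean_totals = c(1e5, 1e5))
  de <- call_pairwise(expr, "a", "b")

  # 0/0 gene excluded from the testing family
  expect_false("g1" %in% de$gene_id)
  expect_equal(nrow(de), 4L)

  # raw max < 10 can never be DE regardless of p
  g2 <- de[de$gene_id == "g2", ]
  expect_false(g2$passes_raw)
  expect_false(g2$is_DE)

  # equal counts: p = 1, not DE
  g3 <- de[de$gene_id == "g3", ]
  expect_equal(g3$p_value, 1)
  expect_equal(g3$log2_ratio, 0)

  # zero-count side uses the one-tag TPM floor, ratio stays finite
  g4 <- de[de$gene_id == "g4", ]
  expect_equal(g4$log2_ratio, log2(1 / 100))
  expect_true(is.finite(g4$log2_ratio))

  # strong change with large counts passes everything
  g5 <- de[de$gene_id == "g5", ]
  expect_true(g5$is_DE)
  expect_equal(g5$log2_ratio, log2(10))

  expect_gte(min(de$fdr - de$p_value), 0)
  expect_error(call_pairwise(expr, "a", "a"), "itself")
  expect_error(call_pairwise(expr, "a", "zzz"), "unknown library")
})

test_that("union_degs keeps any-comparison hits with directions", {
  counts <- cbind(t1 = c(100L, 20L, 30L), t2 = c(100L, 22L, 30L),
                  t3 = c(2L, 21L, 31L))
  rownames(counts) <- c("down_g", "null_g", "null_h")
  expr <- make_expr(counts, clean_totals = rep(1e5, 3))
  all_pw <- call_all_pairwise(expr)
  expect_equal(length(all_pw), 3L)
  degs <- union_degs(all_pw)
  expect_true("down_g" %in% degs$gene_id)
  expect_false("null_g" %in% degs$gene_id)
  expect_equal(degs$direction[degs$gene_id == "down_g"], "down")

  # baseline design restricts the comparison set
  base_pw <- call_all_pairwise(expr, baseline = "t1")
  expect_equal(length(base_pw), 2L)
  expect_true(all(grepl("^t1_vs_", names(base_pw))))
})

test_that("pairwise DE table echoes thresholds in its header", {
  counts <- cbind(a = c(60L, 5L), b = c(2L, 5L))
  rownames(counts) <- c("g1", "g2")
  expr <- make_expr(counts, clean_totals = c(1e5, 1e5))
  de <- call_pairwise(expr, "a", "b",
                      de_thresholds(fdr = 0.001, log2_ratio = 2,
                                    min_raw = 10))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pairwise_de(de, path)
  hdr <- grep("^#", readLines(path), value = TRUE)
  expect_true(any(grepl("fdr<=0.001 \\|log2\\|>=2 raw>=10", hdr)))
  back <- read_tsv(path)
  expect_equal(back$gene_id, de$gene_id)
  expect_equal(back$p_value, de$p_value)
})
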