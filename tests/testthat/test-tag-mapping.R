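# Tag assignment (exact-first, <=1 mismatch, gene-level ambiguity),
# per-gene counting, summary fractions and TPM normalization.

test_that("assign_tag implements the exact-first <=1-mismatch semantics", {
  t0 <- rand_tag()
  t_far <- mutate_at(mutate_at(t0, 8), 15)
  lib <- ref_df(c(t0, mutate_at(t0, 6)), c("g1", "g2"))
  idx <- build_tag_index(lib)

  # exact match to one gene wins even with a 1-mismatch neighbour present
  expect_equal(assign_tag(t0, idx)$status, "unambiguous")
  expect_equal(assign_tag(t0, idx)$gene_id, "g1")

  # distance 1 from tags of two genes -> ambiguous
  alts <- setdiff(c("A", "C", "G", "T"), substring(t0, 6, 6))[1:2]
  lib2 <- ref_df(c(mutate_at(t0, 6, alts[1]), mutate_at(t0, 6, alts[2])),
                 c("g1", "g2"))
  a2 <- assign_tag(t0, build_tag_index(lib2))
  expect_equal(a2$status, "ambiguous")

  # distance 2 from everything -> unmapped
  expect_equal(assign_tag(t_far, build_tag_index(ref_df(t0, "g1")))$status,
               "unmapped")

  # malformed tags are rejected, never silently dropped
  expect_equal(assign_tag("AAAA", idx)$status, "rejected")
  expect_equal(assign_tag(paste0("TTTT", substring(t0, 5)), idx)$status,
               "rejected")

  # two sites of the same gene do not create ambiguity
  lib3 <- ref_df(c(t0, mutate_at(t0, 9)), c("g1", "g1"),
                 site_rank = c(1L, 2L))
  expect_equal(assign_tag(mutate_at(t0, 9), build_tag_index(lib3))$status,
               "unambiguous")
})

test_that("assign_tags agrees with the brute-force Hamming oracle", {
  set.seed(31)
  pool <- substring(rand_tag(12), 5)
  lib <- ref_df(rand_tag(80, pool),
                sample(sprintf("g%02d", 1:40), 80, replace = TRUE))
  idx <- build_tag_index(lib)
  queries <- c(rand_tag(60, pool), rand_tag(20),
               vapply(rand_tag(20, pool), mutate_at, character(1),
                      pos = sample(5:21, 1)))
  got <- assign_to_string(assign_tags(queries, idx))
  want <- vapply(queries, assign_oracle, character(1), lib = lib)
  expect_equal(got, unname(want))
})

test_that("adding genes never turns an ambiguous tag unambiguous", {
  set.seed(37)
  pool <- substring(rand_tag(6), 5)
  lib <- ref_df(rand_tag(40, pool),
                sample(sprintf("g%02d", 1:20), 40, replace = TRUE))
  extra <- ref_df(rand_tag(20, pool), sprintf("h%02d", 1:20))
  queries <- unique(rand_tag(50, pool))
  before <- assign_tags(queries, build_tag_index(lib))$status
  after <- assign_tags(queries, build_tag_index(rbind(lib, extra)))$status
  expect_false(any(before == "ambiguous" & after == "unambiguous"))
  # and unambiguous can only stay or become ambiguous, never unmapped
  expect_false(any(before == "unambiguous" & after == "unmapped"))
})

test_that("count_library conserves copies and recovers simulator truth", {
  cfg <- sim_config(genes_per_genome = 40L, cds_length = 100L,
                    homeolog_fraction = 0, library_size = 20000L,
                    error_rate = 0, seed = 8L)
  g <- simulate_genomes(cfg)
  genes <- c(g$genes_A$gene_id, g$genes_D$gene_id)
  tr <- simulate_trajectories(genes, cfg)
  lib <- build_reference_library(g$genes_A, g$genes_D)
  idx <- build_tag_index(lib)
  tags <- simulate_tag_library(g, tr, 2L, cfg)
  res <- count_library(tags, idx)

  co <- res$summary$copies
  expect_equal(co$unambiguous + co$ambiguous + co$unmapped + co$rejected,
               unname(tags$clean_total))

  # zero error, no homeologs: per-gene counts equal generator truth
  truth <- attr(tags, "truth")
  want <- tapply(truth$count, truth$gene_id, sum)
  expect_equal(res$gene_counts[names(want)],
               setNames(as.integer(want), names(want)))
})

test_that("single-gene error-free library maps completely", {
  cfg <- sim_config(genes_per_genome = 1L, cds_length = 60L,
                    homeolog_fraction = 0, library_size = 5000L,
                    error_rate = 0, seed = 12L,
                    pattern_probs = c(flat = 1, down = 0, up = 0, peak = 0))
  g <- simulate_genomes(cfg)
  tr <- simulate_trajectories(g$genes_A$gene_id, cfg)
  lib <- extract_genome_tags(g$genes_A, "A")
  tags <- simulate_tag_library(g, tr, 1L, cfg)
  res <- count_library(tags, build_tag_index(
    merge_genomes(lib, lib[0, ])))
  expect_equal(unname(res$gene_counts[g$genes_A$gene_id[1]]),
               unname(tags$clean_total))
  expect_equal(res$summary$frac_distinct_gene, 1.0)
})

test_that("TPM follows raw * 1e6 / clean_total with raw preserved", {
  counts <- cbind(lib1 = c(50L, 3L, 0L), lib2 = c(10L, 0L, 7L))
  rownames(counts) <- c("g1", "g2", "g3")
  expr <- make_expr(counts, clean_totals = c(1e6, 4.3e6))
  expect_equal(expr$tpm["g1", "lib1"], 50)
  expect_equal(expr$tpm["g2", "lib1"], 3)
  expect_equal(expr$tpm["g3", "lib1"], 0)
  # raw 3 against 4.3 million clean tags
  expr2 <- make_expr(counts[, c(2, 1)], clean_totals = c(4.3e6, 1e6))
  expect_equal(expr2$tpm["g3", "lib2"], 7 * 1e6 / 4.3e6,
               tolerance = 1e-12)
  expect_equal(round(3 * 1e6 / 4.3e6, 4), 0.6977)
  expect_identical(expr$counts, counts)

  bad <- expr
  bad$clean_totals["lib1"] <- 0
  expect_error(normalize_tpm(bad), "lib1")
})

test_that("expression matrix TSV round-trips", {
  counts <- cbind(`15d` = c(5L, 0L), `25d` = c(2L, 9L))
  rownames(counts) <- c("gA", "gB")
  expr <- make_expr(counts, clean_totals = c(1000, 2000))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(expr, path)
  back <- read_expression_matrix(path)
  expect_identical(back$counts, expr$counts)
  expect_equal(back$tpm, expr$tpm)
  expect_equal(back$clean_totals, expr$clean_totals)
})

test_that("empty tag set yields an empty result without error", {
  lib <- ref_df(rand_tag(3), c("g1", "g2", "g3"))
  empty <- structure(list(library_id = "x",
                          counts = setNames(integer(0), character(0)),
                          clean_total = 0L),
                     class = "tag_count_set")
  res <- count_library(empty, build_tag_index(lib))
  expect_equal(length(res$gene_counts), 0L)
  expect_equal(res$summary$copies$unambiguous, 0L)
})
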