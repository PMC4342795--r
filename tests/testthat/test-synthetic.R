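# Synthetic-data generator: determinism, homeolog divergence control,
# trajectory truth, and the tag sampling/error model.

small_cfg <- function(...) {
  args <- list(genes_per_genome = 10L, cds_length = 60L,
               library_size = 2000L, error_rate = 0, seed = 42L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("simulate_genomes controls homeolog divergence exactly", {
  # divergence 0: homeolog canonical tags identical
  cfg0 <- small_cfg(homeolog_fraction = 0.5,
                    divergence_probs = c("0" = 1))
  g0 <- simulate_genomes(cfg0)
  expect_equal(nrow(g0$homeolog_map), 5L)
  ct <- cottonDGE:::canonical_tags(g0)
  tags <- setNames(ct$tag, ct$gene_id)
  expect_true(all(tags[g0$homeolog_map$gene_A] ==
                  tags[g0$homeolog_map$gene_D]))

  # divergence 1: canonical tags differ at exactly one position
  cfg1 <- small_cfg(homeolog_fraction = 1,
                    divergence_probs = c("1" = 1))
  g1 <- simulate_genomes(cfg1)
  ct1 <- cottonDGE:::canonical_tags(g1)
  tags1 <- setNames(ct1$tag, ct1$gene_id)
  d <- mapply(function(a, b) hamming_matrix(a, b)[1, 1],
              tags1[g1$homeolog_map$gene_A],
              tags1[g1$homeolog_map$gene_D])
  expect_true(all(d == 1L))

  # every CDS yields at least one extractable tag
  tagsA <- extract_genome_tags(g1$genes_A, "A")
  expect_setequal(unique(tagsA$gene_id), g1$genes_A$gene_id)
})

test_that("generator is deterministic under a fixed seed", {
  cfg <- small_cfg(homeolog_fraction = 0.3, error_rate = 0.05)
  g1 <- simulate_genomes(cfg); g2 <- simulate_genomes(cfg)
  expect_identical(g1, g2)
  t1 <- simulate_trajectories(g1$genes_A$gene_id, cfg)
  t2 <- simulate_trajectories(g2$genes_A$gene_id, cfg)
  expect_identical(t1, t2)
  l1 <- simulate_tag_library(g1, t1, 1L, cfg)
  l2 <- simulate_tag_library(g2, t2, 1L, cfg)
  expect_identical(l1, l2)
})

test_that("sim_config rejects invalid parameter combinations", {
  expect_error(small_cfg(divergence_probs = c("20" = 1)),
               "exceeds the 17-nt tag suffix")
  expect_error(small_cfg(error_rate = 0.5))
  expect_error(small_cfg(pattern_probs = c(flat = 0.5, down = 0.2,
                                           up = 0.2, peak = 0.2)),
               "sum to 1")
})

test_that("trajectories match their pattern labels and DE truth rule", {
  cfg <- small_cfg(genes_per_genome = 200L)
  genes <- sprintf("g%03d", 1:400)
  tr <- simulate_trajectories(genes, cfg)
  ab <- as.matrix(tr[, paste0("t", 1:6)])
  expect_true(all(ab > 0))

  flat <- ab[tr$pattern == "flat", , drop = FALSE]
  expect_true(all(abs(flat - flat[, 1]) < 1e-12))
  expect_true(all(!tr$is_DE_truth[tr$pattern == "flat"]))

  down <- ab[tr$pattern == "down", , drop = FALSE]
  expect_true(all(diff(t(down)) < 0))
  up <- ab[tr$pattern == "up", , drop = FALSE]
  expect_true(all(diff(t(up)) > 0))

  # de_fold_range >= 4 makes every non-flat gene DE truth
  ratio <- apply(ab, 1, max) / apply(ab, 1, min)
  expect_equal(tr$is_DE_truth, ratio >= 4)
  expect_true(all(tr$is_DE_truth[tr$pattern != "flat"]))
})

test_that("pattern mixture proportions follow the configured binomial", {
  cfg <- sim_config(genes_per_genome = 500L,
                    pattern_probs = c(flat = 0, down = 0.5,
                                      up = 0.5, peak = 0),
                    seed = 99L)
  tr <- simulate_trajectories(sprintf("g%04d", 1:1000), cfg)
  n_down <- sum(tr$pattern == "down")
  # binomial 99% bounds for n = 1000, p = 0.5
  expect_gte(n_down, qbinom(0.005, 1000, 0.5))
  expect_lte(n_down, qbinom(0.995, 1000, 0.5))
})

test_that("tag sampling conserves library size and respects abundances", {
  cfg <- small_cfg(genes_per_genome = 2L, homeolog_fraction = 0,
                   library_size = 100000L,
                   pattern_probs = c(flat = 1, down = 0, up = 0, peak = 0))
  g <- simulate_genomes(cfg)
  # single gene: all tags identical to its canonical tag
  tr1 <- simulate_trajectories(g$genes_A$gene_id[1], cfg)
  lib1 <- simulate_tag_library(g, tr1, 1L, cfg)
  expect_equal(length(lib1$counts), 1L)
  expect_equal(unname(lib1$clean_total), 100000L)
  ct <- cottonDGE:::canonical_tags(g)
  expect_equal(names(lib1$counts),
               ct$tag[ct$gene_id == g$genes_A$gene_id[1]])

  # two genes at 3:1 abundance: multinomial 99% CI around 0.75
  tr2 <- simulate_trajectories(g$genes_A$gene_id[1:2], cfg)
  for (tc in paste0("t", 1:6)) tr2[[tc]] <- c(3, 1)
  lib2 <- simulate_tag_library(g, tr2, 1L, cfg)
  expect_equal(sum(lib2$counts), 100000L)
  truth <- attr(lib2, "truth")
  n1 <- truth$count[truth$gene_id == g$genes_A$gene_id[1]]
  expect_gte(n1, qbinom(0.005, 100000, 0.75))
  expect_lte(n1, qbinom(0.995, 100000, 0.75))
})

test_that("per-base error rate produces the closed-form error fraction", {
  cfg <- small_cfg(genes_per_genome = 1L, homeolog_fraction = 0,
                   library_size = 50000L, error_rate = 0.01,
                   pattern_probs = c(flat = 1, down = 0, up = 0, peak = 0))
  g <- simulate_genomes(cfg)
  tr <- simulate_trajectories(g$genes_A$gene_id[1], cfg)
  lib <- simulate_tag_library(g, tr, 1L, cfg)
  canon <- cottonDGE:::canonical_tags(g)$tag[1]
  frac_err <- 1 - lib$counts[[canon]] / lib$clean_total
  p_expect <- 1 - (1 - 0.01)^21  # ~0.19
  expect_gte(frac_err, qbinom(0.005, 50000, p_expect) / 50000)
  expect_lte(frac_err, qbinom(0.995, 50000, p_expect) / 50000)
})

test_that("truth linkage: distinct tags map to one gene at zero error", {
  cfg <- small_cfg(genes_per_genome = 50L, homeolog_fraction = 0)
  g <- simulate_genomes(cfg)
  tr <- simulate_trajectories(c(g$genes_A$gene_id, g$genes_D$gene_id), cfg)
  lib <- simulate_tag_library(g, tr, 3L, cfg)
  truth <- attr(lib, "truth")
  expect_true(all(table(truth$tag) == 1L))
  expect_equal(sum(truth$count), lib$clean_total)
})

test_that("write_synthetic_run emits a complete, readable file set", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(genes_per_genome = 5L, n_timepoints = 3L,
                   timepoint_labels = c("15d", "25d", "35d"),
                   library_size = 500L)
  paths <- write_synthetic_run(cfg, dir)
  expect_true(all(file.exists(unlist(paths))))
  genes <- read_cds_fasta(paths$fasta_A)
  expect_equal(nrow(genes), 5L)
  expect_true(all(genes$genome == "A"))
  tags <- read_tag_counts(paths$tags[2])
  expect_equal(tags$library_id, "25d")
  expect_equal(unname(tags$clean_total), 500L)
  manifest <- jsonlite::read_json(paths$manifest)
  expect_equal(manifest$config$seed, 42L)
})
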