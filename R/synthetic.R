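# Ground-truthed synthetic data emulating a six-time-point NlaIII DGE
# study of leaf senescence in an AD allotetraploid sampled against its two
# diploid progenitor genomes (A and D).
#
# The generator's world: each gene is a random coding sequence with one
# guaranteed CATG site >= 17 nt from the 3' end, a fraction of genes occur
# as homeologous A/D pairs whose divergence is confined to the 21-nt tag
# region, expression follows down/up/peak/flat trajectories over six time
# points, and each library is a multinomial sample of 3'-most tags with
# i.i.d. per-base sequencing error.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator.  Defaults describe
#' a desk-scale version of the study design: six time points, two
#' homeologous diploid genomes, libraries of 1e5 clean tags (the real
#' libraries run to millions; `library_size` scales up if wanted), and
#' ~1% per-base sequencing error.
#'
#' @param genes_per_genome number of genes simulated in each genome.
#' @param cds_length length (nt) of each simulated coding sequence.
#' @param homeolog_fraction fraction of genome-A genes that have a
#'   homeologous partner in genome D.
#' @param divergence_probs named numeric vector giving the distribution of
#'   per-pair substitution counts within the 17-nt tag suffix; names are
#'   the substitution counts ("0", "1", ...).
#' @param n_timepoints number of sequencing libraries (time points).
#' @param timepoint_labels labels for the libraries, oldest leaf last.
#' @param library_size clean tags per library.
#' @param error_rate per-base sequencing error probability, in [0, 0.25].
#' @param pattern_probs named mixture over trajectory patterns
#'   (`flat`, `down`, `up`, `peak`); must sum to 1.
#' @param de_fold_range range of the max/min abundance fold for non-flat
#'   trajectories (sampled log-uniformly).
#' @param dirichlet_overdispersion if non-NULL, a positive concentration
#'   scale adding Dirichlet noise to per-library gene proportions
#'   (default NULL: pure multinomial, matching the Poisson-like sampling
#'   assumption of the two-library exact test).
#' @param seed master random seed; every derived stage seed is recorded in
#'   outputs.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(genes_per_genome = 2000L,
                       cds_length = 500L,
                       homeolog_fraction = 0.3,
                       divergence_probs = c("0" = 0.25, "1" = 0.5, "2" = 0.25),
                       n_timepoints = 6L,
                       timepoint_labels = c("15d", "25d", "35d",
                                            "45d", "55d", "65d"),
                       library_size = 100000L,
                       error_rate = 0.01,
                       pattern_probs = c(flat = 0.70, down = 0.15,
                                         up = 0.12, peak = 0.03),
                       de_fold_range = c(4, 16),
                       dirichlet_overdispersion = NULL,
                       seed = 1L) {
  cfg <- list(genes_per_genome = as.integer(genes_per_genome),
              cds_length = as.integer(cds_length),
              homeolog_fraction = homeolog_fraction,
              divergence_probs = divergence_probs,
              n_timepoints = as.integer(n_timepoints),
              timepoint_labels = timepoint_labels,
              library_size = as.integer(library_size),
              error_rate = error_rate,
              pattern_probs = pattern_probs,
              de_fold_range = de_fold_range,
              dirichlet_overdispersion = dirichlet_overdispersion,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$genes_per_genome >= 0L,
            cfg$cds_length >= TAG_LEN + 2L,
            cfg$homeolog_fraction >= 0, cfg$homeolog_fraction <= 1,
            cfg$n_timepoints >= 1L,
            length(cfg$timepoint_labels) == cfg$n_timepoints,
            cfg$library_size >= 0L,
            cfg$error_rate >= 0, cfg$error_rate <= 0.25,
            all(cfg$pattern_probs >= 0),
            cfg$seed >= 0L)
  if (abs(sum(cfg$pattern_probs) - 1) > 1e-8) {
    stop("pattern_probs must sum to 1")
  }
  div <- as.integer(names(cfg$divergence_probs))
  if (any(is.na(div)) || any(div < 0)) {
    stop("divergence_probs names must be non-negative substitution counts")
  }
  if (any(div > SUFFIX_LEN)) {
    stop("requested homeolog divergence exceeds the 17-nt tag suffix length")
  }
  if (abs(sum(cfg$divergence_probs) - 1) > 1e-8) {
    stop("divergence_probs must sum to 1")
  }
  invisible(cfg)
}

# Build one CDS whose 3'-most qualifying CATG site is guaranteed: a random
# prefix, then CATG, then a random 17-nt suffix flush with the 3' end.  Any
# CATG arising by chance inside the suffix has < 17 nt downstream and
# therefore never outranks the injected site.
make_cds <- function(n, cds_length) {
  prefix_len <- cds_length - TAG_LEN
  prefix <- random_dna(n, prefix_len)
  suffix <- random_dna(n, SUFFIX_LEN)
  paste0(prefix, TAG_ANCHOR, suffix)
}

# Apply `k` substitutions to the 17-nt suffix of a tag-bearing CDS,
# at distinct positions chosen uniformly, each to a different base.
diverge_suffix <- function(cds, k) {
  if (k == 0L) return(cds)
  len <- nchar(cds)
  pos <- len - SUFFIX_LEN + sample.int(SUFFIX_LEN, k) - 1L
  ch <- strsplit(cds, "", fixed = TRUE)[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Simulate a pair of homeologous diploid genomes
#'
#' Genome A and genome D each carry `genes_per_genome` coding sequences.
#' A configurable fraction of A genes have a D homeolog: a copy of the A
#' sequence whose 17-nt tag suffix carries a configured number of
#' substitutions (divergence outside the tag region is irrelevant to tag
#' profiling and is not simulated).  The remaining genes in each genome
#' are independent random sequences.
#'
#' @param config a [sim_config()].
#' @return object of class `genome_pair`: list with data.frames `genes_A`
#'   and `genes_D` (columns `gene_id`, `cds`), data.frame `homeolog_map`
#'   (columns `gene_A`, `gene_D`, `divergence`), and the `seed` used.
#' @export
simulate_genomes <- function(config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, 101L), {
    n <- config$genes_per_genome
    ids_A <- sprintf("GA_%05d", seq_len(n))
    ids_D <- sprintf("GD_%05d", seq_len(n))
    cds_A <- make_cds(n, config$cds_length)

    n_hom <- round(config$homeolog_fraction * n)
    hom_idx <- if (n_hom > 0) sort(sample.int(n, n_hom)) else integer(0)
    div_counts <- as.integer(names(config$divergence_probs))
    cds_D <- make_cds(n, config$cds_length)
    divergence <- integer(0)
    if (n_hom > 0) {
      divergence <- sample(div_counts, n_hom, replace = TRUE,
                           prob = config$divergence_probs)
      for (i in seq_len(n_hom)) {
        cds_D[hom_idx[i]] <- diverge_suffix(cds_A[hom_idx[i]], divergence[i])
      }
    }
    out <- list(genes_A = data.frame(gene_id = ids_A, cds = cds_A,
                                     stringsAsFactors = FALSE),
                genes_D = data.frame(gene_id = ids_D, cds = cds_D,
                                     stringsAsFactors = FALSE),
                homeolog_map = data.frame(gene_A = ids_A[hom_idx],
                                          gene_D = ids_D[hom_idx],
                                          divergence = divergence,
                                          stringsAsFactors = FALSE),
                seed = config$seed)
    class(out) <- "genome_pair"
    out
  })
}

# Noise-free trajectory templates over t = 1..T, scaled so max/min = fold.
trajectory_shape <- function(pattern, fold, T) {
  t <- seq_len(T)
  switch(pattern,
         flat = rep(1, T),
         down = fold^(-(t - 1) / (T - 1)),
         up = fold^((t - 1) / (T - 1)),
         peak = {
           peak_at <- ceiling(T / 2)
           d <- abs(t - peak_at) / max(peak_at - 1, T - peak_at)
           fold^(-d) * fold  # rises to `fold`, falls back
         },
         stop("unknown pattern: ", pattern))
}

#' Simulate per-gene expression trajectories
#'
#' Assigns each gene a trajectory pattern (flat, monotone down, monotone
#' up, or peak-shaped) and a strictly positive abundance vector over the
#' configured time points.  Non-flat genes get a max/min fold drawn
#' log-uniformly from `de_fold_range`; base abundance is log-normal so
#' libraries span the realistic dynamic range of tag counts.  A gene is
#' flagged `is_DE_truth` iff its max/min abundance ratio is >= 4, the
#' four-fold cut-off used by the differential-expression stage.
#'
#' @param genes character vector of gene ids.
#' @param config a [sim_config()].
#' @return data.frame of class `trajectory_truth`: `gene_id`, `pattern`,
#'   abundance columns `t1..tT`, `is_DE_truth`.
#' @export
simulate_trajectories <- function(genes, config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, 202L), {
    n <- length(genes)
    T <- config$n_timepoints
    pattern <- sample(names(config$pattern_probs), n, replace = TRUE,
                      prob = config$pattern_probs)
    base <- stats::rlnorm(n, meanlog = 0, sdlog = 1.2)
    lo <- log(config$de_fold_range[1]); hi <- log(config$de_fold_range[2])
    fold <- exp(stats::runif(n, lo, hi))
    ab <- matrix(0, nrow = n, ncol = T,
                 dimnames = list(genes, paste0("t", seq_len(T))))
    for (i in seq_len(n)) {
      ab[i, ] <- base[i] * trajectory_shape(pattern[i], fold[i], T)
    }
    ratio <- apply(ab, 1, max) / apply(ab, 1, min)
    out <- data.frame(gene_id = genes, pattern = pattern,
                      ab, is_DE_truth = ratio >= 4,
                      stringsAsFactors = FALSE, row.names = NULL)
    class(out) <- c("trajectory_truth", "data.frame")
    out
  })
}

#' Extract the 3'-most (canonical) tag of each gene in a genome pair
#' @keywords internal
canonical_tags <- function(genomes) {
  both <- rbind(cbind(genomes$genes_A, genome = "A"),
                cbind(genomes$genes_D, genome = "D"))
  tag <- substr(both$cds, nchar(both$cds) - TAG_LEN + 1L, nchar(both$cds))
  data.frame(gene_id = both$gene_id, genome = both$genome, tag = tag,
             stringsAsFactors = FALSE)
}

# Mutate `k` erroneous copies of tags: each receives >= 1 substitution,
# with the error count drawn from Binomial(21, e) truncated to >= 1.
mutate_tags <- function(tags, error_rate) {
  k <- length(tags)
  if (k == 0L) return(tags)
  p_m <- stats::dbinom(1:TAG_LEN, TAG_LEN, error_rate)
  n_err <- sample.int(TAG_LEN, k, replace = TRUE, prob = p_m)
  ch <- matrix(unlist(strsplit(tags, "", fixed = TRUE)),
               nrow = k, byrow = TRUE)
  for (i in seq_len(k)) {
    pos <- sample.int(TAG_LEN, n_err[i])
    for (p in pos) {
      ch[i, p] <- sample(setdiff(DNA_BASES, ch[i, p]), 1L)
    }
  }
  apply(ch, 1, paste, collapse = "")
}

#' Simulate one sequencing library of clean tags
#'
#' Tags are drawn multinomially from the genes' 3'-most tags in proportion
#' to their abundance at the requested time point, then each copy is
#' independently mutated per base at the configured error rate.  The
#' ground-truth gene of origin of every distinct observed tag is recorded
#' in the `truth` attribute for oracle tests.
#'
#' @param genomes a `genome_pair` from [simulate_genomes()].
#' @param truth a `trajectory_truth` data.frame covering the sampled genes.
#' @param timepoint integer index (1-based) of the library to simulate.
#' @param config a [sim_config()].
#' @return object of class `tag_count_set`: list with `library_id`,
#'   `counts` (named integer vector, tag -> copy number) and
#'   `clean_total`; attribute `truth` is a data.frame (tag, gene_id,
#'   count) linking observed tags to generating genes.
#' @export
simulate_tag_library <- function(genomes, truth, timepoint, config) {
  validate_sim_config(config)
  if (timepoint < 1L || timepoint > config$n_timepoints) {
    stop("timepoint out of range 1..", config$n_timepoints)
  }
  ctags <- canonical_tags(genomes)
  ctags <- ctags[match(truth$gene_id, ctags$gene_id), ]
  if (anyNA(ctags$gene_id)) stop("truth table names genes absent from genomes")
  if (nrow(ctags) == 0L) stop("no taggable genes to sample from")

  with_seed(derive_seed(config$seed, 303L + timepoint), {
    ab <- truth[[paste0("t", timepoint)]]
    prob <- ab / sum(ab)
    if (!is.null(config$dirichlet_overdispersion)) {
      a <- prob * config$dirichlet_overdispersion
      g <- stats::rgamma(length(a), shape = a, rate = 1)
      prob <- g / sum(g)
    }
    counts <- as.vector(stats::rmultinom(1, config$library_size, prob))
    gene_of_copy <- rep.int(seq_along(counts), counts)
    tag_of_copy <- ctags$tag[gene_of_copy]

    if (config$error_rate > 0) {
      p_any <- 1 - (1 - config$error_rate)^TAG_LEN
      err <- stats::runif(length(tag_of_copy)) < p_any
      tag_of_copy[err] <- mutate_tags(tag_of_copy[err], config$error_rate)
    }

    truth_df <- stats::aggregate(
      list(count = rep.int(1L, length(tag_of_copy))),
      by = list(tag = tag_of_copy, gene_id = ctags$gene_id[gene_of_copy]),
      FUN = sum)
    truth_df <- truth_df[order(truth_df$tag, truth_df$gene_id), ]
    rownames(truth_df) <- NULL

    tab <- table(tag_of_copy)
    counts_out <- stats::setNames(as.integer(tab), names(tab))
    out <- list(library_id = config$timepoint_labels[timepoint],
                counts = counts_out,
                clean_total = sum(counts_out),
                seed = config$seed)
    attr(out, "truth") <- truth_df
    class(out) <- "tag_count_set"
    out
  })
}

#' Simulate a qPCR Ct table from an expression matrix
#'
#' Emulates the validation experiment: for each selected gene, technical
#' triplicate Ct values are generated so that the underlying relative
#' expression is a noisy copy of the gene's TPM profile (Gaussian noise of
#' standard deviation `sigma` on the log2 scale, i.e. on Ct units), with a
#' constant-expression reference gene.
#'
#' @param expr an `expression_matrix` (see [normalize_tpm()]).
#' @param genes genes to assay; must be rows of `expr`.
#' @param sigma Ct-scale noise standard deviation.
#' @param reference_gene label used for the reference rows.
#' @param n_replicates technical replicates per gene x sample.
#' @param seed random seed.
#' @return data.frame (gene, sample, replicate, ct) including reference
#'   rows, suitable for [ddct()].
#' @export
simulate_qpcr <- function(expr, genes, sigma = 0.2,
                          reference_gene = "actin",
                          n_replicates = 3L, seed = 1L) {
  stopifnot(inherits(expr, "expression_matrix"))
  missing <- setdiff(genes, rownames(expr$tpm))
  if (length(missing)) {
    stop("genes absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  samples <- colnames(expr$tpm)
  with_seed(seed, {
    rows <- list()
    ref_ct <- 15  # constant reference gene
    for (g in genes) {
      tpm <- expr$tpm[g, ]
      tpm[tpm == 0] <- min(tpm[tpm > 0], 1) / 2  # detection floor
      # target Ct: higher expression -> lower Ct; arbitrary offset 25
      base_ct <- 25 - log2(tpm / mean(tpm))
      for (s in seq_along(samples)) {
        ct <- base_ct[s] + stats::rnorm(n_replicates, 0, sigma)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, sample = samples[s],
          replicate = seq_len(n_replicates), ct = ct,
          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = reference_gene, sample = samples[s],
          replicate = seq_len(n_replicates),
          ct = ref_ct + stats::rnorm(n_replicates, 0, sigma / 4),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out <- unique(out[order(out$gene, out$sample, out$replicate), ])
    rownames(out) <- NULL
    out
  })
}

#' Build an annotation table from trajectory truth
#'
#' Creates a GMT-style annotation set for the synthetic world: one term
#' per trajectory pattern (genes grouped by their generating pattern) plus
#' optional random decoy terms, so the enrichment stage has both truly
#' enriched and null terms to test against.
#'
#' @param truth a `trajectory_truth` data.frame.
#' @param n_decoys number of random decoy terms.
#' @param decoy_size genes per decoy term.
#' @param seed random seed.
#' @return annotation data.frame (term, name, gene_id) of class
#'   `annotation_table`; namespace label stored in attribute `namespace`.
#' @export
simulate_annotation <- function(truth, n_decoys = 20L, decoy_size = 50L,
                                seed = 1L) {
  with_seed(seed, {
    rows <- lapply(unique(truth$pattern), function(p) {
      data.frame(term = paste0("PATTERN_", toupper(p)),
                 name = paste0("genes with ", p, " trajectory"),
                 gene_id = truth$gene_id[truth$pattern == p],
                 stringsAsFactors = FALSE)
    })
    for (i in seq_len(n_decoys)) {
      rows[[length(rows) + 1L]] <- data.frame(
        term = sprintf("DECOY_%03d", i),
        name = sprintf("random gene set %d", i),
        gene_id = sample(truth$gene_id, min(decoy_size, nrow(truth))),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    attr(out, "namespace") <- "synthetic"
    class(out) <- c("annotation_table", "data.frame")
    out
  })
}

#' Write the full synthetic dataset to a directory
#'
#' Emits the FASTA, truth, tag-count and manifest files that downstream
#' stages consume through their declared file interfaces.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return named list of written paths, invisibly.
#' @export
write_synthetic_run <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- simulate_genomes(config)
  all_genes <- c(genomes$genes_A$gene_id, genomes$genes_D$gene_id)
  truth <- simulate_trajectories(all_genes, config)
  h <- config_hash(unclass(config))

  paths <- list(
    fasta_A = file.path(out_dir, "genome_A.fasta"),
    fasta_D = file.path(out_dir, "genome_D.fasta"),
    truth = file.path(out_dir, "trajectory_truth.tsv"),
    homeologs = file.path(out_dir, "homeolog_map.tsv"),
    manifest = file.path(out_dir, "sim_manifest.json"))
  write_cds_fasta(genomes$genes_A, "A", paths$fasta_A)
  write_cds_fasta(genomes$genes_D, "D", paths$fasta_D)
  write_tsv(truth, paths$truth, tsv_provenance(h, "trajectory ground truth"))
  write_tsv(genomes$homeolog_map, paths$homeologs,
            tsv_provenance(h, "homeolog pairs with tag-region divergence"))

  tag_paths <- character(config$n_timepoints)
  for (tp in seq_len(config$n_timepoints)) {
    lib <- simulate_tag_library(genomes, truth, tp, config)
    tag_paths[tp] <- file.path(out_dir,
                               paste0("tags_", lib$library_id, ".tsv"))
    write_tag_counts(lib, tag_paths[tp], comments = tsv_provenance(h))
  }
  paths$tags <- tag_paths

  jsonlite::write_json(list(config = unclass(config), config_hash = h,
                            files = paths),
                       paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
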