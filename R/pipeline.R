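# End-to-end orchestration.
#
# run_all() executes simulate -> build-lib -> map -> de -> cluster ->
# enrich -> qpcr through the stages' declared file interfaces, under a
# single config and master seed, and records a manifest (config snapshot,
# version, per-stage output checksums, wall-clock).  Outputs are
# idempotent under identical config + seed; the manifest itself contains
# timings and is excluded from byte-level comparisons.

#' Pipeline run configuration
#'
#' @param out_dir output directory.
#' @param sim a [sim_config()] driving the synthetic stage (ignored when
#'   external inputs are supplied via `inputs`).
#' @param inputs optional named list of pre-existing input paths
#'   (`fasta_A`, `fasta_D`, `tags` (vector), `annotation`, `qpcr`); any
#'   stage whose inputs are absent and cannot be simulated fails
#'   pre-flight.
#' @param thresholds a [de_thresholds()] list.
#' @param k number of K-means clusters (default 42; clamped to the DEG
#'   count with a warning when fewer DEGs are found at desk scale).
#' @param enrichment_alpha significance level on corrected p.
#' @param canonical_only restrict the mapping database to 3'-most tags.
#' @param stages character vector of stages to run.
#' @param qpcr_sigma Ct noise for the simulated validation experiment.
#' @param n_qpcr_genes genes assayed in the simulated qPCR stage.
#' @param seed master seed (also seeds `sim` unless set there).
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       sim = sim_config(seed = seed),
                       inputs = list(),
                       thresholds = de_thresholds(),
                       k = 42L,
                       enrichment_alpha = 0.05,
                       canonical_only = FALSE,
                       stages = c("simulate", "build-lib", "map", "de",
                                  "cluster", "enrich", "qpcr"),
                       qpcr_sigma = 0.2,
                       n_qpcr_genes = 21L,
                       seed = 1L) {
  stopifnot(k >= 1L, enrichment_alpha > 0, enrichment_alpha < 1)
  structure(list(out_dir = out_dir, sim = sim, inputs = inputs,
                 thresholds = thresholds, k = as.integer(k),
                 enrichment_alpha = enrichment_alpha,
                 canonical_only = canonical_only,
                 stages = stages, qpcr_sigma = qpcr_sigma,
                 n_qpcr_genes = as.integer(n_qpcr_genes),
                 seed = as.integer(seed)),
            class = "run_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full DGE pipeline
#'
#' @param config a [run_config()].
#' @return the run manifest (also written to `manifest.json` in
#'   `out_dir`), invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  # hash captures the scientific configuration, not filesystem locations,
  # so identical configs hash identically wherever the run lands
  cfg_for_hash <- strip_classes(config)
  cfg_for_hash$out_dir <- NULL
  cfg_for_hash$inputs <- NULL
  manifest <- list(config = strip_classes(config),
                   config_hash = config_hash(cfg_for_hash),
                   version = as.character(utils::packageVersion("cottonDGE")),
                   stages = list())
  t_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- fn()
    dt <- proc.time()[["elapsed"]] - t0
    files <- res$files %||% character(0)
    manifest$stages[[name]] <<- list(
      status = "done", seconds = round(dt, 3),
      outputs = as.list(tools::md5sum(unlist(files))))
    res
  }
  paths <- config$inputs

  # pre-flight: every requested stage must have obtainable inputs
  needs_sim <- !("simulate" %in% stages)
  if (needs_sim) {
    need <- c("fasta_A", "fasta_D", "tags")
    missing <- setdiff(need, names(paths))
    if (any(c("build-lib", "map") %in% stages) && length(missing)) {
      stop("pre-flight: stage inputs missing (", paste(missing,
           collapse = ", "), ") and simulate stage is disabled")
    }
    for (p in unlist(paths[intersect(need, names(paths))])) {
      if (!file.exists(p)) stop("pre-flight: input not found: ", p)
    }
    if ("fasta_A" %in% names(paths)) {
      # fail before any computation if the FASTA is unreadable
      tryCatch(invisible(Biostrings::readDNAStringSet(paths$fasta_A)),
               error = function(e) {
                 stop("pre-flight: corrupt FASTA ", paths$fasta_A, ": ",
                      conditionMessage(e))
               })
    }
  }

  if ("simulate" %in% stages) {
    stage_log("simulate", "generating synthetic dataset")
    sim_paths <- t_stage("simulate", function() {
      p <- write_synthetic_run(config$sim, file.path(config$out_dir, "sim"))
      list(files = p)
    })$files
    paths <- utils::modifyList(sim_paths, paths)
  } else {
    manifest$stages[["simulate"]] <- list(status = "skipped")
  }

  lib <- NULL
  if ("build-lib" %in% stages) {
    stage_log("build-lib", "building reference tag library")
    lib <- t_stage("build-lib", function() {
      genes_A <- read_cds_fasta(paths$fasta_A)
      genes_D <- read_cds_fasta(paths$fasta_D)
      l <- build_reference_library(genes_A, genes_D,
                                   canonical_only = config$canonical_only)
      lp <- file.path(config$out_dir, "reference_library.tsv")
      write_reference_library(l, lp)
      list(files = list(library = lp, provenance = paste0(lp,
           ".provenance.tsv")), lib = l)
    })$lib
  } else {
    manifest$stages[["build-lib"]] <- list(status = "skipped")
  }

  expr <- NULL
  if ("map" %in% stages) {
    if (is.null(lib)) stop("pre-flight: map stage requires build-lib")
    stage_log("map", "mapping ", length(paths$tags), " libraries")
    expr <- t_stage("map", function() {
      index <- build_tag_index(lib)
      results <- lapply(paths$tags, function(tp) {
        count_library(read_tag_counts(tp), index)
      })
      e <- expression_matrix(results)
      ep <- file.path(config$out_dir, "expression_matrix.tsv")
      write_expression_matrix(e, ep, tsv_provenance(manifest$config_hash))
      sp <- file.path(config$out_dir, "mapping_summary.tsv")
      summ <- do.call(rbind, lapply(results, function(r) {
        data.frame(library = r$library_id,
                   clean_total = r$summary$clean_total,
                   distinct_tags = r$summary$distinct_tags,
                   unambiguous_copies = r$summary$copies$unambiguous,
                   ambiguous_copies = r$summary$copies$ambiguous,
                   unmapped_copies = r$summary$copies$unmapped,
                   rejected_copies = r$summary$copies$rejected,
                   frac_distinct_gene = r$summary$frac_distinct_gene,
                   frac_distinct_reference =
                     r$summary$frac_distinct_reference,
                   stringsAsFactors = FALSE)
      }))
      write_tsv(summ, sp, tsv_provenance(manifest$config_hash))
      list(files = list(expression = ep, summary = sp), expr = e)
    })$expr
  } else {
    manifest$stages[["map"]] <- list(status = "skipped")
  }

  degs <- NULL
  if ("de" %in% stages) {
    if (is.null(expr)) stop("pre-flight: de stage requires map")
    stage_log("de", "pairwise comparisons")
    degs <- t_stage("de", function() {
      all_pw <- call_all_pairwise(expr, config$thresholds)
      de_dir <- file.path(config$out_dir, "de")
      dir.create(de_dir, showWarnings = FALSE)
      files <- list()
      for (nm in names(all_pw)) {
        f <- file.path(de_dir, paste0(nm, ".tsv"))
        write_pairwise_de(all_pw[[nm]], f)
        files[[nm]] <- f
      }
      d <- union_degs(all_pw)
      dp <- file.path(config$out_dir, "degs.tsv")
      write_tsv(as.data.frame(d), dp,
                tsv_provenance(manifest$config_hash,
                               paste0("union DEG set over ",
                                      length(all_pw), " comparisons")))
      files$degs <- dp
      list(files = files, degs = d)
    })$degs
    stage_log("de", nrow(degs), " DEGs")
  } else {
    manifest$stages[["de"]] <- list(status = "skipped")
  }

  assignment <- NULL
  if ("cluster" %in% stages) {
    if (is.null(degs)) stop("pre-flight: cluster stage requires de")
    if (nrow(degs) < 2L) {
      warning("fewer than 2 DEGs; clustering skipped")
      manifest$stages[["cluster"]] <- list(status = "skipped")
    } else {
      k <- config$k
      if (k > nrow(degs)) {
        warning("k = ", k, " exceeds DEG count ", nrow(degs),
                "; clamping")
        k <- nrow(degs)
      }
      stage_log("cluster", "k-means k=", k, " on ", nrow(degs), " DEGs")
      assignment <- t_stage("cluster", function() {
        prof <- build_profiles(expr, degs, transform = "zscore")
        a <- kmeans_cluster(prof, k, seed = derive_seed(config$seed, 701L))
        a <- classify_cluster_types(a)
        hc <- hierarchical_cluster(prof)
        cp <- file.path(config$out_dir, "clusters.tsv")
        write_clusters(a, cp, leaf_order = hc$leaf_order)
        list(files = list(clusters = cp,
                          means = paste0(cp, ".means.tsv"),
                          leaforder = paste0(cp, ".leaforder.txt")),
             assignment = a)
      })$assignment
    }
  } else {
    manifest$stages[["cluster"]] <- list(status = "skipped")
  }

  if ("enrich" %in% stages) {
    if (is.null(degs)) stop("pre-flight: enrich stage requires de")
    stage_log("enrich", "over-representation test")
    t_stage("enrich", function() {
      anno <- if (!is.null(paths$annotation)) {
        read_gmt(paths$annotation)
      } else {
        truth <- read_tsv(paths$truth)
        simulate_annotation(truth, seed = derive_seed(config$seed, 801L))
      }
      background <- rownames(expr$counts)
      enr <- fisher_enrich(degs$gene_id, background, anno,
                           alpha = config$enrichment_alpha)
      ep <- file.path(config$out_dir, "enrichment.tsv")
      write_tsv(as.data.frame(enr), ep,
                tsv_provenance(manifest$config_hash,
                               paste0("alpha=", config$enrichment_alpha)))
      dirs <- summarize_directions(degs, anno)
      dp <- file.path(config$out_dir, "term_directions.tsv")
      write_tsv(dirs, dp, tsv_provenance(manifest$config_hash))
      list(files = list(enrichment = ep, directions = dp))
    })
  } else {
    manifest$stages[["enrich"]] <- list(status = "skipped")
  }

  if ("qpcr" %in% stages) {
    if (is.null(expr)) stop("pre-flight: qpcr stage requires map")
    stage_log("qpcr", "platform cross-validation")
    t_stage("qpcr", function() {
      calib <- colnames(expr$tpm)[1]
      if (!is.null(paths$qpcr)) {
        ct <- read_ct_table(paths$qpcr)
      } else {
        cand <- if (!is.null(degs) && nrow(degs) > 0) degs$gene_id
                else rownames(expr$tpm)
        gsel <- utils::head(cand, config$n_qpcr_genes)
        ct <- simulate_qpcr(expr, gsel, sigma = config$qpcr_sigma,
                            seed = derive_seed(config$seed, 901L))
      }
      rel <- ddct(ct, calibrator = calib)
      rp <- file.path(config$out_dir, "qpcr_rel_expr.tsv")
      write_tsv(as.data.frame(rel), rp,
                tsv_provenance(manifest$config_hash,
                               paste0("calibrator=", calib)))
      corr <- correlate_platforms(rel, expr)
      cp <- file.path(config$out_dir, "qpcr_correlation.tsv")
      write_tsv(corr$per_gene, cp,
                tsv_provenance(manifest$config_hash,
                               paste0("mean_r=", corr$mean_r)))
      list(files = list(rel_expr = rp, correlation = cp))
    })
  } else {
    manifest$stages[["qpcr"]] <- list(status = "skipped")
  }

  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommand dispatcher used by the `inst/cli/cotton-dge` script; takes
#' a character vector so it is testable without spawning a process.
#' Subcommands: simulate, build-lib, map, de, cluster, enrich, qpcr,
#' run-all.  Common flags: `--out DIR`, `--seed INT`, `--fdr`, `--log2`,
#' `--min-raw`, `--k`, `--canonical-only`, `--genes`, `--library-size`,
#' `--error-rate`, `--skip STAGE` (repeatable).
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
dge_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cotton-dge <subcommand> [--out DIR] [--seed INT] [options]",
    "subcommands: run-all simulate build-lib map de cluster enrich qpcr",
    sep = "\n")
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  opts <- parse_cli_flags(args[-1])
  seed <- as.integer(opts$seed %||% 1L)
  out <- opts$out %||% "dge_out"

  sim <- sim_config(
    genes_per_genome = as.integer(opts$genes %||% 2000L),
    library_size = as.integer(opts$`library-size` %||% 100000L),
    error_rate = as.numeric(opts$`error-rate` %||% 0.01),
    seed = seed)
  th <- de_thresholds(fdr = as.numeric(opts$fdr %||% 0.001),
                      log2_ratio = as.numeric(opts$log2 %||% 2),
                      min_raw = as.integer(opts$`min-raw` %||% 10L))
  all_stages <- c("simulate", "build-lib", "map", "de", "cluster",
                  "enrich", "qpcr")
  stages <- switch(cmd,
    "run-all" = setdiff(all_stages, opts$skip %||% character(0)),
    "simulate" = "simulate",
    "build-lib" = c("simulate", "build-lib"),
    "map" = c("simulate", "build-lib", "map"),
    "de" = c("simulate", "build-lib", "map", "de"),
    "cluster" = c("simulate", "build-lib", "map", "de", "cluster"),
    "enrich" = c("simulate", "build-lib", "map", "de", "enrich"),
    "qpcr" = c("simulate", "build-lib", "map", "de", "qpcr"),
    { cat(usage, "\n"); stop("unknown subcommand: ", cmd) })

  inputs <- list()
  for (key in c("fasta_A", "fasta_D", "annotation", "qpcr")) {
    flag <- gsub("_", "-", key)
    if (!is.null(opts[[flag]])) inputs[[key]] <- opts[[flag]]
  }
  if (!is.null(opts$tags)) {
    inputs$tags <- strsplit(opts$tags, ",", fixed = TRUE)[[1]]
    stages <- setdiff(stages, "simulate")
  }

  cfg <- run_config(out_dir = out, sim = sim, inputs = inputs,
                    thresholds = th,
                    k = as.integer(opts$k %||% 42L),
                    canonical_only = isTRUE(opts$`canonical-only`),
                    stages = stages, seed = seed)
  run_all(cfg)
  invisible(0L)
}

# "--flag value" and bare "--flag" (logical) parser; repeated flags
# accumulate into vectors.
parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      opts[[key]] <- c(opts[[key]], args[i + 1L])
      i <- i + 2L
    } else {
      opts[[key]] <- TRUE
      i <- i + 1L
    }
  }
  opts
}
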