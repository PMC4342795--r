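# Time-course clustering of DEG expression profiles.
#
# Profiles are log2(TPM + floor), optionally row-standardized.  K-means
# uses a seeded k-means++ initialization and Lloyd iterations with
# deterministic empty-cluster re-seeding, so runs are exactly
# reproducible.  Clusters are classified into trajectory types: type_I
# (downregulated over the course), type_II (upregulated), or complex
# (e.g. an initial increase followed by a decrease).

#' Build a profile matrix for clustering
#'
#' @param expr an `expression_matrix`.
#' @param degs a `deg_set` (or character vector of gene ids).
#' @param transform "log2" (default) or "zscore" (log2 then per-row
#'   standardization; constant rows become all-zero).
#' @param floor pseudo-TPM added before the log (default 1).
#' @return object of class `profile_matrix`: list with numeric matrix
#'   `values` (genes x time points), `log2` (pre-standardization log2
#'   matrix) and the `transform` label.
#' @export
build_profiles <- function(expr, degs, transform = c("log2", "zscore"),
                           floor = 1) {
  transform <- match.arg(transform)
  genes <- if (is.data.frame(degs)) degs$gene_id else degs
  missing <- setdiff(genes, rownames(expr$tpm))
  if (length(missing)) {
    stop("DEG genes absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  lg <- log2(expr$tpm[genes, , drop = FALSE] + floor)
  values <- lg
  if (transform == "zscore") {
    mu <- rowMeans(lg)
    sdev <- apply(lg, 1, stats::sd)
    values <- (lg - mu) / ifelse(sdev > 0, sdev, 1)
  }
  structure(list(values = values, log2 = lg, transform = transform,
                 floor = floor),
            class = "profile_matrix")
}

# Squared Euclidean distances from each row of X to each row of centers.
row_dist2 <- function(X, centers) {
  d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") -
    2 * X %*% t(centers)
  pmax(d2, 0)
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, nrow = k, ncol = ncol(X))
  first <- sample.int(n, 1)
  centers[1, ] <- X[first, ]
  if (k > 1) {
    d2 <- row_dist2(X, centers[1, , drop = FALSE])[, 1]
    for (c in 2:k) {
      if (all(d2 == 0)) {
        pick <- sample.int(n, 1)
      } else {
        pick <- sample.int(n, 1, prob = d2 / sum(d2))
      }
      centers[c, ] <- X[pick, ]
      d2 <- pmin(d2, row_dist2(X, centers[c, , drop = FALSE])[, 1])
    }
  }
  centers
}

#' Seeded K-means clustering of expression profiles
#'
#' Lloyd iterations from a k-means++ initialization under a fixed seed.
#' An emptied cluster is re-seeded from the point farthest from its
#' assigned center.  Final cluster ids are relabelled by descending
#' early-time-point mean (mean of the first two columns of the cluster
#' mean profile) so that downregulated clusters come first, mirroring the
#' usual presentation of senescence time courses.
#'
#' @param profiles a `profile_matrix`.
#' @param k number of clusters (1 <= k <= number of genes).
#' @param seed random seed.
#' @param max_iter maximum Lloyd iterations.
#' @return object of class `cluster_assignment`: list with `cluster`
#'   (named integer vector gene -> cluster id), `centers` (k x T matrix
#'   in profile space), `mean_log2` (k x T cluster means of the log2
#'   profiles), `withinss_trace` (objective per iteration), `k`, `seed`.
#' @export
kmeans_cluster <- function(profiles, k, seed = 1L, max_iter = 100L) {
  stopifnot(inherits(profiles, "profile_matrix"))
  X <- profiles$values
  n <- nrow(X)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k (", k, ") exceeds the number of genes (", n, ")")

  with_seed(seed, {
    centers <- kmeanspp_init(X, k)
    assign_old <- rep(0L, n)
    trace <- numeric(0)
    for (iter in seq_len(max_iter)) {
      d2 <- row_dist2(X, centers)
      assign_new <- max.col(-d2, ties.method = "first")
      # re-seed empty clusters from the farthest point
      for (c in which(tabulate(assign_new, nbins = k) == 0L)) {
        far <- which.max(d2[cbind(seq_len(n), assign_new)])
        assign_new[far] <- c
        centers[c, ] <- X[far, ]
      }
      trace <- c(trace, sum(d2[cbind(seq_len(n), assign_new)]))
      for (c in seq_len(k)) {
        centers[c, ] <- colMeans(X[assign_new == c, , drop = FALSE])
      }
      if (identical(assign_new, assign_old)) break
      assign_old <- assign_new
    }
    # relabel by descending early mean so "down" clusters lead
    mean_log2 <- t(vapply(seq_len(k), function(c) {
      colMeans(profiles$log2[assign_new == c, , drop = FALSE])
    }, numeric(ncol(X))))
    early <- rowMeans(mean_log2[, 1:min(2, ncol(X)), drop = FALSE])
    relabel <- order(early, decreasing = TRUE)
    new_id <- integer(k)
    new_id[relabel] <- seq_len(k)
    cluster <- stats::setNames(new_id[assign_new], rownames(X))
    centers <- centers[relabel, , drop = FALSE]
    mean_log2 <- mean_log2[relabel, , drop = FALSE]
    rownames(centers) <- rownames(mean_log2) <- seq_len(k)
    colnames(mean_log2) <- colnames(X)

    structure(list(cluster = cluster, centers = centers,
                   mean_log2 = mean_log2, withinss_trace = trace,
                   k = k, seed = seed),
              class = "cluster_assignment")
  })
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering (default average linkage, Euclidean
#' distance); the returned leaf order is deterministic and usable to
#' order heat-map rows.
#'
#' @param profiles a `profile_matrix`.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return list with the `hclust` tree and `leaf_order` (gene ids).
#' @export
hierarchical_cluster <- function(profiles, linkage = "average") {
  stopifnot(inherits(profiles, "profile_matrix"))
  X <- profiles$values
  if (nrow(X) < 2L) stop("hierarchical clustering needs at least 2 genes")
  hc <- stats::hclust(stats::dist(X, method = "euclidean"),
                      method = linkage)
  list(tree = hc, leaf_order = rownames(X)[hc$order])
}

#' Classify clusters into trajectory types
#'
#' A cluster is `type_I` (downregulated) when its mean log2 profile drops
#' from the early phase (mean of the first two time points) to the late
#' phase (mean of the last two) by at least `log2(fold_threshold)` and
#' trends monotonically down (Spearman correlation of the mean profile
#' with time <= -trend_cutoff); `type_II` is the symmetric upward case;
#' anything else (e.g. peak-shaped: an initial increase followed by a
#' decrease) is `complex`.
#'
#' @param assignment a `cluster_assignment`.
#' @param fold_threshold early/late fold change required (default 2).
#' @param trend_cutoff Spearman trend magnitude required (default 0.5).
#' @return the assignment with added `cluster_type` (named character
#'   vector per cluster) and `gene_type` (per gene).
#' @export
classify_cluster_types <- function(assignment, fold_threshold = 2,
                                   trend_cutoff = 0.5) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  M <- assignment$mean_log2
  T <- ncol(M)
  t_idx <- seq_len(T)
  lfold <- log2(fold_threshold)
  types <- vapply(seq_len(nrow(M)), function(c) {
    prof <- M[c, ]
    early <- mean(prof[1:min(2, T)])
    late <- mean(prof[max(1, T - 1):T])
    rho <- suppressWarnings(
      stats::cor(prof, t_idx, method = "spearman"))
    if (is.na(rho)) rho <- 0
    if (late - early <= -lfold && rho <= -trend_cutoff) "type_I"
    else if (late - early >= lfold && rho >= trend_cutoff) "type_II"
    else "complex"
  }, character(1))
  names(types) <- rownames(M)
  assignment$cluster_type <- types
  assignment$gene_type <- stats::setNames(
    types[as.character(assignment$cluster)], names(assignment$cluster))
  assignment
}

#' Write cluster assignment (gene, cluster, type) and cluster means
#'
#' @param assignment a classified `cluster_assignment`.
#' @param path output TSV for per-gene assignments; cluster means go to
#'   `<path>.means.tsv` and the heat-map leaf order (if supplied) to
#'   `<path>.leaforder.txt`.
#' @param leaf_order optional gene ordering from [hierarchical_cluster()].
#' @return `path`, invisibly.
#' @export
write_clusters <- function(assignment, path, leaf_order = NULL) {
  df <- data.frame(gene_id = names(assignment$cluster),
                   cluster = as.integer(assignment$cluster),
                   type = assignment$gene_type %||%
                     rep(NA_character_, length(assignment$cluster)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$cluster, df$gene_id), ]
  write_tsv(df, path, tsv_provenance(extra = paste0("k=", assignment$k,
                                                    " seed=", assignment$seed)))
  means <- data.frame(cluster = rownames(assignment$mean_log2),
                      type = assignment$cluster_type %||% NA_character_,
                      assignment$mean_log2, check.names = FALSE,
                      stringsAsFactors = FALSE)
  write_tsv(means, paste0(path, ".means.tsv"),
            tsv_provenance(extra = "cluster mean log2 profiles"))
  if (!is.null(leaf_order)) {
    writeLines(leaf_order, paste0(path, ".leaforder.txt"))
  }
  invisible(path)
}
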