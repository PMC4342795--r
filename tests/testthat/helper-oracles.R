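# Independent brute-force oracles and small fixture builders.  Oracles
# deliberately avoid the package's own code paths (wildcard-key indexes,
# log-space tails, step-up shortcuts) so agreement is evidence.

# --- sequence fixtures ------------------------------------------------

rand_tag <- function(n = 1, suffix_pool = NULL) {
  mk <- function() {
    suf <- if (is.null(suffix_pool)) {
      paste(sample(c("A", "C", "G", "T"), 17, replace = TRUE),
            collapse = "")
    } else {
      sample(suffix_pool, 1)
    }
    paste0("CATG", suf)
  }
  vapply(seq_len(n), function(i) mk(), character(1))
}

mutate_at <- function(tag, pos, base = NULL) {
  ch <- strsplit(tag, "")[[1]]
  if (is.null(base)) base <- setdiff(c("A", "C", "G", "T"), ch[pos])[1]
  ch[pos] <- base
  paste(ch, collapse = "")
}

# a CDS whose canonical tag is exactly `tag` (tag flush with the 3' end)
cds_with_tag <- function(tag, prefix_len = 30) {
  paste0(paste(rep("T", prefix_len), collapse = ""), tag)
}

# small reference library data.frame from explicit (tag, gene) pairs
ref_df <- function(tags, genes, genome = "A", site_rank = 1L) {
  data.frame(tag = tags, gene_id = genes,
             genome = rep(genome, length.out = length(tags)),
             site_rank = rep(site_rank, length.out = length(tags)),
             stringsAsFactors = FALSE)
}

# manually constructed expression matrix (bypasses tag mapping)
make_expr <- function(counts, clean_totals = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(clean_totals)) clean_totals <- colSums(counts)
  clean_totals <- stats::setNames(as.numeric(clean_totals),
                                  colnames(counts))
  out <- list(counts = counts, tpm = NULL, clean_totals = clean_totals)
  class(out) <- "expression_matrix"
  normalize_tpm(out)
}

# --- Hamming / tag-library oracles -----------------------------------

# full pairwise Hamming distance matrix between two tag vectors,
# computed column-by-column over a character matrix (no wildcard keys)
hamming_matrix <- function(a, b) {
  A <- matrix(unlist(strsplit(a, "")), nrow = length(a), byrow = TRUE)
  B <- matrix(unlist(strsplit(b, "")), nrow = length(b), byrow = TRUE)
  D <- matrix(0L, nrow = length(a), ncol = length(b))
  for (p in seq_len(ncol(A))) {
    D <- D + outer(A[, p], B[, p], "!=")
  }
  D
}

# O(n^2) reference-merge oracle: drop every D gene whose canonical tag is
# within Hamming distance <= 1 of any A canonical tag (A priority)
merge_oracle <- function(tags_A, tags_D) {
  canon_A <- tags_A[tags_A$site_rank == 1L, , drop = FALSE]
  canon_D <- tags_D[tags_D$site_rank == 1L, , drop = FALSE]
  dropped <- character(0)
  if (nrow(canon_A) && nrow(canon_D)) {
    D <- hamming_matrix(canon_D$tag, canon_A$tag)
    dropped <- unique(canon_D$gene_id[apply(D <= 1L, 1, any)])
  }
  keep <- rbind(tags_A, tags_D[!(tags_D$gene_id %in% dropped), ])
  keep <- keep[order(keep$genome, keep$gene_id, keep$site_rank), ]
  rownames(keep) <- NULL
  keep
}

# brute-force single-tag assignment against an explicit Hamming scan
assign_oracle <- function(tag, lib) {
  if (nchar(tag) != 21 || !grepl("^[ACGT]+$", tag) ||
      !startsWith(tag, "CATG")) {
    return("rejected")
  }
  d <- as.vector(hamming_matrix(tag, lib$tag))
  exact_genes <- unique(lib$gene_id[d == 0L])
  if (length(exact_genes) == 1L) return(paste0("unambiguous:", exact_genes))
  if (length(exact_genes) >= 2L) return("ambiguous")
  near_genes <- unique(lib$gene_id[d == 1L])
  if (length(near_genes) == 1L) return(paste0("unambiguous:", near_genes))
  if (length(near_genes) >= 2L) return("ambiguous")
  "unmapped"
}

assign_to_string <- function(asg) {
  ifelse(asg$status == "unambiguous",
         paste0("unambiguous:", asg$gene_id), asg$status)
}

# --- statistics oracles ----------------------------------------------

# Audic-Claverie probability by the term recurrence
# p(0|x) = (1+r)^-(x+1);  p(y|x) = p(y-1|x) * r/(1+r) * (x+y)/y
# (independent of the closed-form log-gamma route in the package)
ac_oracle <- function(x, y, N1, N2) {
  r <- N2 / N1
  ymax <- max(y)
  probs <- (1 + r)^-(x + 1)
  if (ymax > 0) {
    fac <- (r / (1 + r)) * (x + seq_len(ymax)) / seq_len(ymax)
    probs <- probs * c(1, cumprod(fac))
  }
  probs[y + 1L]
}

# two-sided p by explicit tail summation
ac_two_sided_oracle <- function(x, y, N1, N2, y_max = 10000L) {
  probs <- ac_oracle(x, 0:y_max, N1, N2)
  lower <- sum(probs[seq_len(y + 1L)])
  upper <- sum(probs[(y + 1L):(y_max + 1L)])
  min(1, 2 * min(lower, upper))
}

# literal step-up Benjamini-Hochberg, loop form
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[ord[i]] * n / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# exhaustive hypergeometric upper tail: P(X >= k) by direct enumeration
hyper_tail_oracle <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# naive average-linkage agglomeration returning the cophenetic matrix
average_linkage_oracle <- function(X) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        d <- mean(D[clusters[[i]], clusters[[j]], drop = FALSE])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    coph[clusters[[i]], clusters[[j]]] <- best[1]
    coph[clusters[[j]], clusters[[i]]] <- best[1]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  coph
}

# explicit sum-based Pearson correlation
pearson_oracle <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) - sum(a) * sum(b) / n
  den <- sqrt((sum(a^2) - sum(a)^2 / n) * (sum(b^2) - sum(b)^2 / n))
  num / den
}
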