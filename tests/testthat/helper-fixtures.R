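# Shared fixtures and independent oracles for the test suite.

# small random study: `n_genes` x `n_samples` gaussian expression plus a
# complete clinical table (events, times, node status)
tiny_study <- function(n_genes = 10, n_samples = 30, seed = 1,
                       gene_names = sprintf("G%02d", seq_len(n_genes))) {
  set.seed(seed)
  expr <- matrix(rnorm(n_genes * n_samples, mean = 7),
                 n_genes, n_samples,
                 dimnames = list(gene_names,
                                 sprintf("S%03d", seq_len(n_samples))))
  clin <- data.frame(sample_id = colnames(expr),
                     recurrence_event = rbinom(n_samples, 1, 0.4),
                     followup_time = rexp(n_samples, 0.2) + 0.01,
                     node_status = rbinom(n_samples, 1, 0.3),
                     cohort = "test", stringsAsFactors = FALSE)
  cohort_study(expr_matrix(expr, cohort = "test"), clin)
}

# literal replay of the greedy edge rule: sort every candidate above the
# threshold by descending rho (ties by seed then partner), then walk the
# list keeping an edge while its partner has spare capacity
oracle_select_edges <- function(cand, threshold, edge_limit) {
  pool <- cand[cand$rho > threshold, , drop = FALSE]
  pool <- pool[order(-pool$rho, pool$seed_gene, pool$partner_gene), ,
               drop = FALSE]
  kept <- pool[0, , drop = FALSE]
  for (i in seq_len(nrow(pool))) {
    used <- sum(kept$partner_gene == pool$partner_gene[i])
    if (used < edge_limit) kept <- rbind(kept, pool[i, ])
  }
  rownames(kept) <- NULL
  kept
}

# naive agglomerative complete linkage on a dissimilarity matrix: merge the
# closest cluster pair (max-linkage) while that distance is at most `h`,
# returning the final partition as an integer assignment
oracle_complete_linkage <- function(d, h) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  repeat {
    if (length(clusters) == 1L) break
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        link <- max(d[clusters[[i]], clusters[[j]]])
        if (link < best_d) {
          best_d <- link
          best <- c(i, j)
        }
      }
    }
    if (best_d > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  out <- integer(nrow(d))
  for (k in seq_along(clusters)) out[clusters[[k]]] <- k
  out
}

# full-tree merge heights of the naive algorithm (to locate the cut point
# independently of hclust)
oracle_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        link <- max(d[clusters[[i]], clusters[[j]]])
        if (link < best_d) {
          best_d <- link
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# are two cluster assignments the same partition (up to label permutation)?
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# write a small expression TSV and return its path
write_expr_tsv <- function(mat, path = tempfile(fileext = ".tsv"),
                           id_col = "gene") {
  df <- data.frame(mat, check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(mat)), id_col), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
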