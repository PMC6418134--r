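#' Spearman correlations of every non-seed gene with the seed genes
#'
#' For each (seed, non-seed) gene pair, computes the Spearman rank
#' correlation of expression across the chosen samples. Seeds absent from
#' the study are reported in a message and skipped; non-seed genes with zero
#' expression variance (undefined ranks) are dropped.
#'
#' @param study A [cohort_study()].
#' @param seeds Character vector of seed (candidate) gene symbols.
#' @param samples Optional character vector restricting to a sample subset
#'   (a phenotype stratum); default all samples.
#' @return Data frame of candidate edges: `seed_gene`, `partner_gene`,
#'   `rho`, ordered by seed then partner.
#' @export
compute_seed_correlations <- function(study, seeds, samples = NULL) {
  expr <- unclass(study$expression)
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(expr))
    if (length(missing_s)) stop("unknown sample(s): ",
                                paste(utils::head(missing_s, 5),
                                      collapse = ", "))
    expr <- expr[, samples, drop = FALSE]
  }
  if (ncol(expr) < 3L)
    stop("need at least 3 samples to estimate correlations (have ",
         ncol(expr), ")")
  present <- seeds %in% rownames(expr)
  if (any(!present))
    message(sum(!present), " seed gene(s) absent and skipped: ",
            paste(utils::head(seeds[!present], 5), collapse = ", "))
  seeds <- seeds[present]
  if (!length(seeds)) stop("none of the seed genes are in the study")
  partners <- setdiff(rownames(expr), seeds)
  if (!length(partners)) stop("no non-seed genes in the study")
  rho <- stats::cor(t(expr[seeds, , drop = FALSE]),
                    t(expr[partners, , drop = FALSE]),
                    method = "spearman")
  out <- data.frame(seed_gene = rep(seeds, times = length(partners)),
                    partner_gene = rep(partners, each = length(seeds)),
                    rho = as.numeric(rho),
                    stringsAsFactors = FALSE)
  out <- out[is.finite(out$rho), , drop = FALSE]
  out <- out[order(out$seed_gene, out$partner_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy edge selection under a per-gene edge limit
#'
#' Implements the network simplification rule: only candidate edges whose
#' correlation exceeds `threshold` are considered; candidates are processed
#' from the highest correlation downward, and an edge is kept only while its
#' non-seed partner still has fewer than `edge_limit` kept edges. Seeds may
#' anchor any number of edges. Ties in `rho` are broken by seed then partner
#' symbol so selection is deterministic.
#'
#' @param candidates Data frame from [compute_seed_correlations()].
#' @param threshold Correlation threshold (edges require `rho > threshold`).
#' @param edge_limit Maximum kept edges per non-seed gene.
#' @param absolute If `TRUE`, threshold and ordering use `|rho|` (signed
#'   correlations above `+threshold` only, by default).
#' @return Data frame of kept edges (`seed_gene`, `partner_gene`, `rho`),
#'   in selection order. May have zero rows.
#' @export
select_edges <- function(candidates, threshold = 0.9, edge_limit = 1L,
                         absolute = FALSE) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (edge_limit < 1L) stop("edge_limit must be >= 1")
  strength <- if (absolute) abs(candidates$rho) else candidates$rho
  pool <- candidates[strength > threshold, , drop = FALSE]
  if (!nrow(pool)) return(pool)
  strength <- if (absolute) abs(pool$rho) else pool$rho
  ord <- order(-strength, pool$seed_gene, pool$partner_gene)
  pool <- pool[ord, , drop = FALSE]
  degree <- new.env(parent = emptyenv())
  keep <- logical(nrow(pool))
  for (i in seq_len(nrow(pool))) {
    p <- pool$partner_gene[i]
    d <- if (is.null(degree[[p]])) 0L else degree[[p]]
    if (d < edge_limit) {
      keep[i] <- TRUE
      degree[[p]] <- d + 1L
    }
  }
  out <- pool[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign network genes to co-expression clusters
#'
#' Agglomerative complete-linkage clustering of the network's genes on the
#' dissimilarity `1 - Spearman(rho)`, with the dendrogram cut at 1/1.5 of
#' its height. `cut = "max"` (default) reads that as (maximum merge
#' height)/1.5; `cut = "total"` as (sum of all merge heights)/1.5, capped at
#' the maximum height. Cluster IDs are renumbered so that cluster 1 contains
#' the alphabetically first gene, cluster 2 the alphabetically first gene
#' not in cluster 1, and so on.
#'
#' @param genes Character vector of network gene symbols.
#' @param study A [cohort_study()] providing expression.
#' @param samples Optional sample subset (the network's stratum).
#' @param cut Dendrogram cut rule, `"max"` or `"total"`.
#' @return Named integer vector of cluster IDs over `genes`.
#' @export
cluster_genes <- function(genes, study, samples = NULL,
                          cut = c("max", "total")) {
  cut <- match.arg(cut)
  if (!length(genes)) stop("no genes to cluster")
  expr <- unclass(study$expression)
  if (!is.null(samples)) expr <- expr[, samples, drop = FALSE]
  missing_g <- setdiff(genes, rownames(expr))
  if (length(missing_g)) stop("gene(s) not in study: ",
                              paste(utils::head(missing_g, 5),
                                    collapse = ", "))
  if (length(genes) == 1L)
    return(stats::setNames(1L, genes))
  rho <- stats::cor(t(expr[genes, , drop = FALSE]), method = "spearman")
  d <- stats::as.dist(1 - rho)
  hc <- stats::hclust(d, method = "complete")
  hmax <- max(hc$height)
  h <- if (cut == "max") hmax / 1.5 else min(sum(hc$height) / 1.5, hmax)
  cl <- stats::cutree(hc, h = h)
  relabel_clusters(cl)
}

# renumber cluster IDs by alphabetical first member, for stable output
relabel_clusters <- function(cl) {
  first <- vapply(split(names(cl), cl), function(g) min(g), character(1))
  new_id <- stats::setNames(rank(first, ties.method = "first"), names(first))
  stats::setNames(as.integer(new_id[as.character(cl)]), names(cl))
}

#' Annotate network nodes with display attributes
#'
#' Applies the icon rules: size is the absolute coefficient of variation
#' (sd/mean of the gene's expression within the stratum); shape is a diamond
#' for seed genes, a star for co-expressed genes whose node-adjusted Cox
#' p-value is below 0.05, and a circle otherwise; the frame is red for
#' 0.01 <= p < 0.05, yellow for p < 0.01, absent otherwise; direction is
#' "up" when mean expression among recurrence cases exceeds that among
#' non-cases (dashed frame line), else "down" (solid line).
#'
#' @param nodes Data frame with columns `gene` and `is_seed`.
#' @param study A [cohort_study()]; direction uses all samples with a
#'   non-missing recurrence event.
#' @param samples Sample subset defining the stratum (for cv).
#' @param cox Data frame with columns `term` and `p` giving each gene's
#'   node-adjusted Cox p-value; required for every non-seed node.
#' @return `nodes` with `cv`, `cox_p`, `shape`, `frame`, `direction` added.
#' @export
annotate_nodes <- function(nodes, study, samples = NULL, cox = NULL) {
  expr <- unclass(study$expression)
  strat <- if (is.null(samples)) expr else expr[, samples, drop = FALSE]
  mu <- rowMeans(strat[nodes$gene, , drop = FALSE])
  if (any(abs(mu) < 1e-8))
    stop("coefficient of variation undefined (near-zero mean) for gene(s): ",
         paste(nodes$gene[abs(mu) < 1e-8], collapse = ", "))
  sdv <- apply(strat[nodes$gene, , drop = FALSE], 1L, stats::sd)
  nodes$cv <- abs(sdv / mu)

  p <- rep(NA_real_, nrow(nodes))
  if (!is.null(cox)) p <- cox$p[match(nodes$gene, cox$term)]
  need <- !nodes$is_seed & is.na(p)
  if (any(need))
    stop("missing Cox p-value for co-expressed gene(s): ",
         paste(nodes$gene[need], collapse = ", "))
  nodes$cox_p <- p

  nodes$shape <- ifelse(nodes$is_seed, "diamond",
                        ifelse(p < 0.05, "star", "circle"))
  nodes$frame <- ifelse(is.na(p) | p >= 0.05, "none",
                        ifelse(p < 0.01, "yellow", "red"))

  ev <- study$clinical$recurrence_event
  has_ev <- !is.na(ev)
  m1 <- rowMeans(expr[nodes$gene, has_ev & ev == 1, drop = FALSE])
  m0 <- rowMeans(expr[nodes$gene, has_ev & ev == 0, drop = FALSE])
  nodes$direction <- ifelse(m1 > m0, "up", "down")
  nodes
}

#' Build one seed-anchored co-expression network
#'
#' Full construction for one sample stratum: correlate every non-seed gene
#' with the seeds, keep edges by the greedy threshold/edge-limit rule,
#' additionally connect the included seeds to each other where their mutual
#' Spearman exceeds the threshold, cluster all network genes, and annotate
#' nodes. Network nodes are the seeds anchoring at least one kept edge plus
#' their selected partners.
#'
#' @inheritParams compute_seed_correlations
#' @inheritParams select_edges
#' @inheritParams cluster_genes
#' @param cox Node-adjusted per-gene Cox results (see [annotate_nodes()]);
#'   computed on the fly for the network's non-seed genes when `NULL`.
#' @param stratum Label stored on the network.
#' @return A `gene_network`: list with `nodes` (gene, is_seed, cv, cox_p,
#'   cluster, shape, frame, direction), `edges` (gene_a, gene_b, rho),
#'   `stratum`, `samples`, `threshold`, `edge_limit`.
#' @export
build_network <- function(study, seeds, samples = NULL, threshold = 0.9,
                          edge_limit = 1L, absolute = FALSE,
                          cut = c("max", "total"), cox = NULL,
                          stratum = "all") {
  cut <- match.arg(cut)
  cand <- compute_seed_correlations(study, seeds, samples)
  kept <- select_edges(cand, threshold = threshold, edge_limit = edge_limit,
                       absolute = absolute)
  used_seeds <- sort(unique(kept$seed_gene))
  partners <- sort(unique(kept$partner_gene))
  edges <- data.frame(gene_a = kept$seed_gene, gene_b = kept$partner_gene,
                      rho = kept$rho, stringsAsFactors = FALSE)

  # seed-seed edges among included seeds, tracked separately from the
  # candidate pool (the per-gene edge limit applies to non-seed genes only)
  if (length(used_seeds) >= 2L) {
    expr <- unclass(study$expression)
    if (!is.null(samples)) expr <- expr[, samples, drop = FALSE]
    sr <- stats::cor(t(expr[used_seeds, , drop = FALSE]),
                     method = "spearman")
    idx <- which(upper.tri(sr), arr.ind = TRUE)
    ss_rho <- sr[idx]
    keep_ss <- if (absolute) abs(ss_rho) > threshold else ss_rho > threshold
    if (any(keep_ss))
      edges <- rbind(edges, data.frame(
        gene_a = used_seeds[idx[keep_ss, 1L]],
        gene_b = used_seeds[idx[keep_ss, 2L]],
        rho = ss_rho[keep_ss], stringsAsFactors = FALSE))
  }

  genes <- c(used_seeds, partners)
  nodes <- data.frame(gene = genes,
                      is_seed = genes %in% seeds,
                      stringsAsFactors = FALSE)
  if (nrow(nodes)) {
    cl <- cluster_genes(genes, study, samples, cut = cut)
    nodes$cluster <- as.integer(cl[nodes$gene])
    if (is.null(cox) && length(partners))
      cox <- screen_genes(study, partners)
    nodes <- annotate_nodes(nodes, study, samples, cox)
    nodes <- nodes[order(nodes$gene), , drop = FALSE]
    rownames(nodes) <- NULL
  } else {
    nodes$cluster <- integer(0)
    nodes$cv <- nodes$cox_p <- numeric(0)
    nodes$shape <- nodes$frame <- nodes$direction <- character(0)
  }
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, stratum = stratum,
                 samples = samples %||% colnames(study$expression),
                 threshold = threshold, edge_limit = edge_limit),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network [%s]: %d nodes (%d seeds), %d edges, rho > %g\n",
              x$stratum, nrow(x$nodes), sum(x$nodes$is_seed),
              nrow(x$edges), x$threshold))
  invisible(x)
}

#' Build networks for each phenotype stratum
#'
#' Splits the study's samples by the requested clinical variables
#' (`"recurrence"`, `"node"`, or both), drops samples missing any grouping
#' variable, and runs the full network construction independently within
#' each stratum. Node annotation (Cox p-values, direction) always uses the
#' full study so that networks are comparable.
#'
#' @inheritParams build_network
#' @param strata Character vector from `c("recurrence", "node")`.
#' @param min_samples Minimum samples a stratum must have (guard against
#'   meaningless correlation estimates).
#' @return Named list of `gene_network` objects; names like `"node+/recur-"`.
#' @export
build_stratum_networks <- function(study, seeds,
                                   strata = c("recurrence", "node"),
                                   threshold = 0.9, edge_limit = 1L,
                                   absolute = FALSE,
                                   cut = c("max", "total"),
                                   min_samples = 20L) {
  cut <- match.arg(cut)
  strata <- match.arg(strata, c("recurrence", "node"), several.ok = TRUE)
  cl <- study$clinical
  parts <- list()
  if ("node" %in% strata) parts$node <- cl$node_status
  if ("recurrence" %in% strata) parts$recur <- cl$recurrence_event
  keep <- Reduce(`&`, lapply(parts, function(v) !is.na(v)))
  lab <- do.call(paste, c(Map(function(nm, v)
    paste0(nm, ifelse(v == 1, "+", "-")), names(parts),
    lapply(parts, function(v) v[keep])), sep = "/"))
  groups <- split(cl$sample_id[keep], lab)

  small <- names(groups)[vapply(groups, length, integer(1)) < min_samples]
  if (length(small))
    stop("stratum below ", min_samples, " samples: ",
         paste(small, collapse = ", "))

  # one shared annotation pass: node-adjusted Cox over every gene that can
  # enter any stratum network would be wasteful; fit lazily per network
  out <- lapply(names(groups), function(g)
    build_network(study, seeds, samples = groups[[g]],
                  threshold = threshold, edge_limit = edge_limit,
                  absolute = absolute, cut = cut, stratum = g))
  names(out) <- names(groups)
  out
}

#' Compare the non-seed gene sets of two networks
#'
#' Set algebra over the co-expressed (non-seed) nodes: genes common to both
#' networks, exclusive to the first, and exclusive to the second. This is
#' the discovery surface for novel genes that change co-expression between
#' phenotype strata.
#'
#' @param a,b `gene_network` objects built over the same gene universe.
#' @return A `network_comparison`: list with `common_genes`,
#'   `exclusive_to_a`, `exclusive_to_b` (sorted character vectors) and the
#'   two stratum labels.
#' @export
compare_networks <- function(a, b) {
  ga <- a$nodes$gene[!a$nodes$is_seed]
  gb <- b$nodes$gene[!b$nodes$is_seed]
  structure(list(stratum_a = a$stratum, stratum_b = b$stratum,
                 common_genes = sort(intersect(ga, gb)),
                 exclusive_to_a = sort(setdiff(ga, gb)),
                 exclusive_to_b = sort(setdiff(gb, ga))),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("network_comparison [%s vs %s]\n", x$stratum_a, x$stratum_b))
  cat("  common:     ", paste(x$common_genes, collapse = ", "), "\n")
  cat("  only", x$stratum_a, ":", paste(x$exclusive_to_a, collapse = ", "),
      "\n")
  cat("  only", x$stratum_b, ":", paste(x$exclusive_to_b, collapse = ", "),
      "\n")
  invisible(x)
}
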