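test_that("seed correlations are rank-based and cover all pairs", {
  s <- tiny_study(n_genes = 6, n_samples = 25, seed = 2,
                  gene_names = c("SEED1", "SEED2", "A", "B", "C", "D"))
  expr <- unclass(s$expression)
  # plant exact monotone relations
  expr["A", ] <- exp(expr["SEED1", ])      # monotone increasing
  expr["B", ] <- -expr["SEED1", ]          # anti-monotone
  expr["C", ] <- expr["SEED2", ]           # identical
  s <- cohort_study(expr_matrix(expr, cohort = "test"), s$clinical)

  cand <- compute_seed_correlations(s, c("SEED1", "SEED2"))
  expect_equal(nrow(cand), 2L * 4L)
  get <- function(sd, p) cand$rho[cand$seed_gene == sd &
                                    cand$partner_gene == p]
  expect_equal(get("SEED1", "A"), 1)
  expect_equal(get("SEED1", "B"), -1)
  expect_equal(get("SEED2", "C"), 1)

  # missing seeds are messaged and skipped
  expect_message(compute_seed_correlations(s, c("SEED1", "NOPE")),
                 "absent")
  # sample guard
  expect_error(
    compute_seed_correlations(s, "SEED1",
                              samples = s$clinical$sample_id[1:2]),
    "at least 3 samples")
})

test_that("Spearman matches a rank-then-Pearson oracle on untied data", {
  set.seed(31)
  for (rep in 1:20) {
    x <- rnorm(40)
    y <- 0.6 * x + rnorm(40)
    expect_equal(cor(x, y, method = "spearman"),
                 cor(rank(x), rank(y), method = "pearson"),
                 tolerance = 1e-12)
  }
})

test_that("greedy edge selection follows the threshold and edge-limit rule", {
  # a partner above threshold with two seeds keeps only its strongest edge
  cand <- data.frame(seed_gene = c("SA", "SB"),
                     partner_gene = c("P1", "P1"),
                     rho = c(0.95, 0.92), stringsAsFactors = FALSE)
  kept <- select_edges(cand, threshold = 0.9, edge_limit = 1)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$seed_gene, "SA")

  # nothing above the threshold gives an empty set
  low <- data.frame(seed_gene = "SA", partner_gene = "P1", rho = 0.9)
  expect_equal(nrow(select_edges(low, threshold = 0.9)), 0L)

  # ties break by seed symbol for determinism
  tie <- data.frame(seed_gene = c("SB", "SA"),
                    partner_gene = c("P1", "P1"),
                    rho = c(0.95, 0.95), stringsAsFactors = FALSE)
  expect_equal(select_edges(tie)$seed_gene, "SA")

  # absolute mode admits strong negative correlations
  negc <- data.frame(seed_gene = "SA", partner_gene = "P1", rho = -0.95)
  expect_equal(nrow(select_edges(negc)), 0L)
  expect_equal(nrow(select_edges(negc, absolute = TRUE)), 1L)

  expect_error(select_edges(cand, threshold = 1.2), "threshold")
  expect_error(select_edges(cand, edge_limit = 0), "edge_limit")
})

test_that("edge selection equals the literal-replay oracle on random instances", {
  set.seed(101)
  for (rep in 1:200) {
    n_seeds <- sample(2:4, 1)
    n_partners <- sample(5:20, 1)
    seeds <- sprintf("S%02d", seq_len(n_seeds))
    partners <- sprintf("P%02d", seq_len(n_partners))
    cand <- expand.grid(seed_gene = seeds, partner_gene = partners,
                        stringsAsFactors = FALSE)
    cand$rho <- round(runif(nrow(cand), 0.5, 1), 2)   # force frequent ties
    lim <- sample(1:2, 1)
    thr <- sample(c(0.8, 0.9), 1)
    got <- select_edges(cand, threshold = thr, edge_limit = lim)
    want <- oracle_select_edges(cand, threshold = thr, edge_limit = lim)
    expect_equal(got[order(got$seed_gene, got$partner_gene), ],
                 want[order(want$seed_gene, want$partner_gene), ],
                 ignore_attr = TRUE)
    # invariants on every output: rho above threshold, degrees within limit
    expect_true(all(got$rho > thr))
    expect_true(all(table(got$partner_gene) <= lim))
  }
})

test_that("raising the threshold never adds edges", {
  set.seed(55)
  cand <- expand.grid(seed_gene = sprintf("S%d", 1:4),
                      partner_gene = sprintf("P%02d", 1:25),
                      stringsAsFactors = FALSE)
  cand$rho <- runif(nrow(cand), 0.5, 1)
  lo <- select_edges(cand, threshold = 0.7, edge_limit = 1)
  hi <- select_edges(cand, threshold = 0.85, edge_limit = 1)
  key <- function(d) paste(d$seed_gene, d$partner_gene)
  expect_true(all(key(hi) %in% key(lo)))
  expect_lte(nrow(hi), nrow(lo))
})

test_that("clustering separates blocks and matches the brute-force linkage", {
  # two internally perfect blocks, independent across blocks
  set.seed(12)
  n <- 40
  u <- rnorm(n); v <- rnorm(n)
  expr <- rbind(A1 = u, A2 = 2 * u + 1, B1 = v, B2 = 3 * v + 2)
  colnames(expr) <- sprintf("S%02d", 1:n)
  clin <- data.frame(sample_id = colnames(expr),
                     recurrence_event = rbinom(n, 1, 0.5),
                     followup_time = rexp(n) + 0.1,
                     node_status = rbinom(n, 1, 0.3))
  s <- cohort_study(expr_matrix(expr + 10), clin)
  cl <- cluster_genes(rownames(expr), s)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(cl[["A1"]], cl[["A2"]])
  expect_equal(cl[["B1"]], cl[["B2"]])
  expect_false(cl[["A1"]] == cl[["B1"]])
  # IDs ordered by alphabetically first member
  expect_equal(cl[["A1"]], 1L)

  # degenerate single gene
  expect_equal(unname(cluster_genes("A1", s)), 1L)

  # oracle equivalence on random instances of 4..8 genes
  set.seed(77)
  done <- 0
  tries <- 0
  while (done < 40 && tries < 200) {
    tries <- tries + 1
    k <- sample(4:8, 1)
    g <- matrix(rnorm(k * 25), k, 25,
                dimnames = list(sprintf("G%d", seq_len(k)),
                                sprintf("S%d", 1:25)))
    rho <- cor(t(g), method = "spearman")
    d <- 1 - rho
    off <- d[upper.tri(d)]
    if (anyDuplicated(round(off, 12))) next   # skip tied dissimilarities
    clin2 <- data.frame(sample_id = colnames(g),
                        recurrence_event = rbinom(25, 1, 0.5),
                        followup_time = rexp(25) + 0.1,
                        node_status = rbinom(25, 1, 0.3))
    st <- cohort_study(expr_matrix(g + 8), clin2)
    got <- cluster_genes(rownames(g), st)
    h <- max(oracle_linkage_heights(stats::as.dist(d))) / 1.5
    want <- oracle_complete_linkage(stats::as.dist(d), h)
    expect_true(same_partition(unname(got[rownames(g)]), want))
    done <- done + 1
  }
  expect_gte(done, 40)
})

test_that("node annotation applies the shape, frame and direction rules", {
  set.seed(91)
  s <- tiny_study(n_genes = 4, n_samples = 40, seed = 91,
                  gene_names = c("SEED1", "GA", "GB", "GC"))
  nodes <- data.frame(gene = c("SEED1", "GA", "GB", "GC"),
                      is_seed = c(TRUE, FALSE, FALSE, FALSE),
                      stringsAsFactors = FALSE)
  cox <- data.frame(term = c("GA", "GB", "GC"), p = c(0.03, 0.005, 0.2))
  ann <- annotate_nodes(nodes, s, cox = cox)
  expect_equal(ann$shape, c("diamond", "star", "star", "circle"))
  expect_equal(ann$frame, c("none", "red", "yellow", "none"))
  expect_true(all(ann$cv >= 0))
  expect_true(all(ann$direction %in% c("up", "down")))

  # direction reflects the event/non-event mean difference
  expr <- unclass(s$expression)
  ev <- s$clinical$recurrence_event == 1
  up <- mean(expr["GA", ev]) > mean(expr["GA", !ev])
  expect_equal(ann$direction[ann$gene == "GA"], if (up) "up" else "down")

  # zero-mean gene breaks the cv and is named
  expr2 <- expr
  expr2["GC", ] <- expr2["GC", ] - mean(expr2["GC", ])
  s2 <- cohort_study(expr_matrix(expr2, cohort = "test"), s$clinical)
  expect_error(annotate_nodes(nodes, s2, cox = cox), "GC")

  # a co-expressed gene without a Cox result is an error
  expect_error(annotate_nodes(nodes, s, cox = cox[-1, ]), "GA")
})

test_that("stratified construction and comparison recover a planted block", {
  cfg <- sim_config(n_samples = 600, n_cohorts = 1, n_genes = 120,
                    rng_seed = 19)
  s <- generate_cohort(cfg, 1)
  nets <- build_stratum_networks(s, cfg$seed_genes, strata = "recurrence")
  expect_length(nets, 2L)
  expect_setequal(names(nets), c("recur+", "recur-"))

  # every network respects the edge invariants
  for (nw in nets) {
    expect_true(all(nw$edges$rho > nw$threshold))
    partner_deg <- table(nw$edges$gene_b[!nw$edges$gene_b %in%
                                           cfg$seed_genes])
    if (length(partner_deg)) expect_true(all(partner_deg <= nw$edge_limit))
  }

  # the planted immunoglobulin block is in both strata's networks
  for (nw in nets) {
    expect_true(all(cfg$block_genes %in% nw$nodes$gene))
  }

  cmpz <- compare_networks(nets[["recur+"]], nets[["recur-"]])
  expect_true(all(cfg$block_genes %in% cmpz$common_genes))
  # comparison sets are disjoint and exhaustive over non-seed nodes
  expect_length(intersect(cmpz$common_genes, cmpz$exclusive_to_a), 0L)
  expect_length(intersect(cmpz$common_genes, cmpz$exclusive_to_b), 0L)
  all_nonseed <- union(
    nets[[1]]$nodes$gene[!nets[[1]]$nodes$is_seed],
    nets[[2]]$nodes$gene[!nets[[2]]$nodes$is_seed])
  expect_setequal(c(cmpz$common_genes, cmpz$exclusive_to_a,
                    cmpz$exclusive_to_b), all_nonseed)

  # identical networks: all common, no exclusives
  self <- compare_networks(nets[[1]], nets[[1]])
  expect_length(self$exclusive_to_a, 0L)
  expect_length(self$exclusive_to_b, 0L)

  # four strata under node x recurrence; small strata are named errors
  expect_error(build_stratum_networks(s, cfg$seed_genes,
                                      min_samples = 5000),
               "below 5000")
})
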