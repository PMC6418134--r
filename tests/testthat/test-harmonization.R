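test_that("expression tables parse, with duplicate and non-numeric guards", {
  m <- matrix(1:6 + 0.5, 3, 2,
              dimnames = list(c("A", "B", "C"), c("S1", "S2")))
  p <- write_expr_tsv(m)
  parsed <- read_expression_table(p)
  expect_equal(dim(parsed), c(3L, 2L))
  expect_equal(unclass(parsed)[, ], m[, ])

  # probe-level tables may repeat row IDs
  mp <- m
  rownames(mp) <- c("probe1", "probe1", "probe2")
  pp <- write_expr_tsv(mp, id_col = "probe")
  probe <- read_expression_table(pp, scale_tag = "probe_level")
  expect_equal(nrow(probe), 3L)
  expect_error(read_expression_table(pp, scale_tag = "gene_level"),
               "duplicate gene IDs")

  # duplicate sample header is always an error
  dup <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS1", "A\t1\t2"), dup)
  expect_error(read_expression_table(dup), "duplicate sample IDs")

  # unparsable cell names its row and column
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "A\t1\t2", "B\tx\t3"), bad)
  expect_error(read_expression_table(bad), "row 'B', column 'S1'")
})

test_that("probe collapse takes per-sample medians and drops unmapped", {
  vals <- matrix(c(1, 2, 3, 4,   # gene X probes (S1)
                   5, 6, 7, 8),  # S2
                 4, 2, dimnames = list(paste0("p", 1:4), c("S1", "S2")))
  m <- expr_matrix(vals, scale_tag = "probe_level")
  map <- data.frame(probe_id = paste0("p", 1:3),
                    gene_symbol = c("X", "X", "X"))
  expect_message(g <- collapse_probes(m, map), "1 unmapped")
  expect_equal(unname(unclass(g)["X", ]), c(2, 6))   # odd-count median

  map4 <- data.frame(probe_id = paste0("p", 1:4),
                     gene_symbol = c("X", "X", "X", "X"))
  g4 <- collapse_probes(m, map4)
  expect_equal(unname(unclass(g4)["X", ]), c(2.5, 6.5))  # even-count median

  map1 <- data.frame(probe_id = "p4", gene_symbol = "Y")
  expect_message(g1 <- collapse_probes(m, map1))
  expect_equal(unname(unclass(g1)["Y", ]), c(4, 8))      # identity

  expect_error(collapse_probes(m, data.frame(probe_id = character(0),
                                             gene_symbol = character(0))),
               "empty")
  amb <- data.frame(probe_id = c("p1", "p1"), gene_symbol = c("X", "Y"))
  expect_error(collapse_probes(m, amb), "more than one gene")
})

test_that("probe collapse is invariant to probe row order", {
  set.seed(4)
  vals <- matrix(rnorm(40), 8, 5,
                 dimnames = list(paste0("p", 1:8), paste0("S", 1:5)))
  map <- data.frame(probe_id = paste0("p", 1:8),
                    gene_symbol = rep(c("A", "B", "C"), c(3, 3, 2)))
  m1 <- expr_matrix(vals, scale_tag = "probe_level")
  perm <- sample(8)
  m2 <- expr_matrix(vals[perm, ], scale_tag = "probe_level")
  expect_equal(unclass(collapse_probes(m1, map))[, ],
               unclass(collapse_probes(m2, map))[, ])
})

test_that("moment alignment matches the reference pooled mean and sd", {
  set.seed(7)
  ref <- expr_matrix(matrix(rnorm(200, 7, 2), 20, 10,
                            dimnames = list(sprintf("G%02d", 1:20),
                                            sprintf("R%02d", 1:10))))

  # already aligned input passes through unchanged
  same <- harmonize_to_reference(ref, ref)
  expect_lt(max(abs(unclass(same) - unclass(ref))), 1e-9)

  # linear-scale target that is exactly 2^reference
  lin_vals <- 2^unclass(ref)
  colnames(lin_vals) <- sprintf("T%02d", 1:10)
  lin <- expr_matrix(lin_vals, cohort = "target")
  out <- harmonize_to_reference(lin, ref, target_scale = "linear")
  pm <- pooled_moments(out)
  pr <- pooled_moments(ref)
  expect_lt(abs(pm[["mean"]] - pr[["mean"]]), 1e-6)
  expect_lt(abs(pm[["sd"]] - pr[["sd"]]), 1e-6)

  # standard-normal target mapped onto mean-7 sd-2 reference
  tgt <- expr_matrix(matrix(rnorm(300), 30, 10,
                            dimnames = list(sprintf("G%02d", 1:30),
                                            sprintf("T%02d", 1:10))))
  out2 <- harmonize_to_reference(tgt, ref)
  pm2 <- pooled_moments(out2)
  expect_lt(abs(pm2[["mean"]] - pr[["mean"]]), 1e-6)
  expect_lt(abs(pm2[["sd"]] - pr[["sd"]]), 1e-6)
  expect_true(is.matrix(attr(out2, "moments")))

  # guards
  flat <- expr_matrix(matrix(5, 3, 4,
                             dimnames = list(letters[1:3], LETTERS[1:4])))
  expect_error(harmonize_to_reference(flat, ref), "zero-variance")
  neg <- expr_matrix(matrix(c(-1, 2, 3, 4, 5, 6), 3, 2,
                            dimnames = list(letters[1:3], c("a", "b"))))
  expect_error(harmonize_to_reference(neg, ref, target_scale = "linear"),
               "non-positive")
})

test_that("harmonization is idempotent", {
  set.seed(8)
  ref <- expr_matrix(matrix(rnorm(200, 6, 1.5), 20, 10,
                            dimnames = list(sprintf("G%02d", 1:20),
                                            sprintf("R%02d", 1:10))))
  tgt <- expr_matrix(matrix(rnorm(200, 2, 3), 20, 10,
                            dimnames = list(sprintf("G%02d", 1:20),
                                            sprintf("T%02d", 1:10))))
  once <- harmonize_to_reference(tgt, ref)
  twice <- harmonize_to_reference(once, ref)
  expect_lt(max(abs(unclass(twice) - unclass(once))), 1e-9)
})

test_that("cohort merge intersects genes and guards sample collisions", {
  s1 <- tiny_study(n_genes = 6, seed = 1,
                   gene_names = c("A", "B", "C", "D", "E", "F"))
  s2 <- tiny_study(n_genes = 4, seed = 2, gene_names = c("A", "B", "X", "Y"))
  s2$clinical$sample_id <- paste0("T", s2$clinical$sample_id)
  colnames(s2$expression) <- s2$clinical$sample_id
  s2 <- cohort_study(expr_matrix(unclass(s2$expression), cohort = "c2"),
                     s2$clinical, provenance = "c2")

  merged <- merge_cohorts(list(s1, s2))
  expect_setequal(rownames(merged$expression), c("A", "B"))
  expect_equal(ncol(merged$expression), 60L)
  expect_equal(merged$provenance, c("test", "c2"))
  # every clinical record pairs with exactly one expression column
  expect_identical(merged$clinical$sample_id, colnames(merged$expression))

  # single study returns unchanged
  expect_identical(merge_cohorts(list(s1)), s1)

  # colliding sample IDs are an error
  expect_error(merge_cohorts(list(s1, s1)), "collision")

  # empty intersection is an error
  s3 <- tiny_study(n_genes = 3, seed = 3, gene_names = c("P", "Q", "R"))
  s3$clinical$sample_id <- paste0("U", s3$clinical$sample_id)
  colnames(s3$expression) <- s3$clinical$sample_id
  s3 <- cohort_study(expr_matrix(unclass(s3$expression), cohort = "c3"),
                     s3$clinical, provenance = "c3")
  expect_error(merge_cohorts(list(s1, s3)), "empty gene intersection")
})

test_that("cohort_study enforces sample alignment and positive follow-up", {
  s <- tiny_study()
  cl <- s$clinical
  expect_error(cohort_study(s$expression, cl[-1, ]), "sample sets differ")
  cl_bad <- cl
  cl_bad$followup_time[3] <- 0
  expect_error(cohort_study(s$expression, cl_bad), "non-positive follow-up")
  # clinical rows get reordered to expression column order
  shuffled <- cl[rev(seq_len(nrow(cl))), ]
  s2 <- cohort_study(s$expression, shuffled)
  expect_identical(s2$clinical$sample_id, colnames(s2$expression))
})
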