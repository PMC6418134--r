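#' Collapse a correlated gene set into a standardized PCA index
#'
#' Each gene's expression is standardized (mean 0, sd 1) across samples, the
#' first principal component of the standardized matrix is extracted, and
#' the component scores are re-standardized to mean 0, sd 1. The component
#' sign is fixed so that scores correlate positively with the gene-set mean
#' expression: a higher index means higher expression of the gene set
#' (protective, for tumor-suppressor-like sets).
#'
#' @param study A [cohort_study()].
#' @param gene_set Character vector of at least two genes present in the
#'   study.
#' @return An `immune_index`: list with `sample_scores` (named numeric,
#'   mean 0 / sd 1), `loadings` (named per-gene weights),
#'   `explained_variance_fraction`, and (after [dichotomize_index()])
#'   `cutoff_percentile`, `cutoff_value`, `group`.
#' @export
compute_immune_index <- function(study, gene_set) {
  if (length(gene_set) < 2L) stop("gene_set needs at least 2 genes")
  expr <- unclass(study$expression)
  missing_g <- setdiff(gene_set, rownames(expr))
  if (length(missing_g)) stop("gene(s) not in study: ",
                              paste(missing_g, collapse = ", "))
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  x <- t(expr[gene_set, , drop = FALSE])          # samples x genes
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene(s): ",
         paste(gene_set[sds == 0], collapse = ", "))
  z <- scale(x)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1L]
  loadings <- pc$rotation[, 1L]
  if (stats::cor(scores, rowMeans(z)) < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  scores <- (scores - mean(scores)) / stats::sd(scores)
  structure(list(sample_scores = stats::setNames(scores, rownames(x)),
                 loadings = stats::setNames(as.numeric(loadings), gene_set),
                 explained_variance_fraction =
                   pc$sdev[1L]^2 / sum(pc$sdev^2),
                 cutoff_percentile = NA_real_,
                 cutoff_value = NA_real_,
                 group = NULL),
            class = "immune_index")
}

#' @export
print.immune_index <- function(x, ...) {
  cat(sprintf(
    "immune_index: %d samples, %d genes, %.1f%% variance on PC1\n",
    length(x$sample_scores), length(x$loadings),
    100 * x$explained_variance_fraction))
  cat(sprintf("  score range %.2f .. %.2f (mean 0, sd 1)\n",
              min(x$sample_scores), max(x$sample_scores)))
  if (!is.null(x$group))
    cat(sprintf("  cut at the %gth percentile (%.3f): %d low / %d high\n",
                x$cutoff_percentile, x$cutoff_value,
                sum(x$group == "low"), sum(x$group == "high")))
  invisible(x)
}

#' Split index scores into low and high groups at a percentile cutoff
#'
#' The cutoff is the empirical percentile of the scores (linear
#' interpolation between order statistics). Samples with a score at or
#' below the cutoff form the `low` group (the reference in the discrete
#' prognostic model); the rest form `high`.
#'
#' @param index An [compute_immune_index()] result.
#' @param percentile Cut point in (0, 100); default the 40th percentile.
#' @return The index with `cutoff_percentile`, `cutoff_value` and per-sample
#'   `group` filled in.
#' @export
dichotomize_index <- function(index, percentile = 40) {
  stopifnot(inherits(index, "immune_index"))
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must be in (0, 100)")
  s <- index$sample_scores
  if (max(s) - min(s) < .Machine$double.eps^0.5)
    stop("all scores identical; cutoff undefined")
  cutoff <- unname(stats::quantile(s, percentile / 100, type = 7))
  index$cutoff_percentile <- percentile
  index$cutoff_value <- cutoff
  index$group <- stats::setNames(
    ifelse(s <= cutoff, "low", "high"), names(s))
  index
}

#' Cox models of recurrence on the immune index
#'
#' Fits the two prognostic layouts: the continuous model regresses the
#' recurrence hazard on the index score plus node status, and the discrete
#' model on the high-vs-low group indicator (low = reference) plus node
#' status. Returns the fitted model alongside the per-term results so
#' survival curves can be predicted from it.
#'
#' @param study A [cohort_study()]; samples must match the index.
#' @param index An `immune_index` (dichotomized, for `mode = "discrete"`).
#' @param mode `"continuous"` or `"discrete"`.
#' @param adjust Adjustment covariates; only `"node"` (or empty) supported.
#' @return An `index_cox_fit`: list with `results` (a `cox_result` with one
#'   row per model term, index term first), `fit` (the `coxph` object),
#'   `mode`, and the model frame `data`.
#' @export
index_cox <- function(study, index, mode = c("continuous", "discrete"),
                      adjust = "node") {
  mode <- match.arg(mode)
  stopifnot(inherits(index, "immune_index"))
  ids <- colnames(study$expression)
  if (!all(ids %in% names(index$sample_scores)))
    stop("index does not cover every study sample")
  cl <- study$clinical
  df <- data.frame(.time = cl$followup_time,
                   .event = cl$recurrence_event)
  if (mode == "continuous") {
    df$index <- as.numeric(index$sample_scores[ids])
    term_label <- "immune_index"
  } else {
    if (is.null(index$group))
      stop("discrete mode needs a dichotomized index; ",
           "run dichotomize_index() first")
    g <- index$group[ids]
    if (length(unique(g)) < 2L)
      stop("all samples fall in one index group")
    df$index <- as.numeric(g == "high")
    term_label <- "high_immune_index"
  }
  use_node <- "node" %in% adjust
  if (use_node) df$node <- cl$node_status
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (sum(df$.event) < 2L) stop("fewer than 2 events")
  fml <- if (use_node) survival::Surv(.time, .event) ~ index + node
         else survival::Surv(.time, .event) ~ index
  fit <- survival::coxph(fml, data = df, ties = "efron")
  summ <- summary(fit)
  co <- summ$coefficients
  ci <- summ$conf.int
  terms <- rownames(co)
  labels <- ifelse(terms == "index", term_label, terms)
  res <- data.frame(term = labels,
                    B = unname(co[, "coef"]),
                    HR = unname(co[, "exp(coef)"]),
                    p = unname(co[, "Pr(>|z|)"]),
                    ci_low = unname(ci[, "lower .95"]),
                    ci_high = unname(ci[, "upper .95"]),
                    covariates = if (use_node) "node" else "",
                    n = nrow(df),
                    n_events = sum(df$.event),
                    n_excluded = nrow(cl) - nrow(df),
                    converged = TRUE,
                    stringsAsFactors = FALSE)
  class(res) <- c("cox_result", "data.frame")
  structure(list(results = res, fit = fit, mode = mode, data = df,
                 adjusted_for_node = use_node),
            class = "index_cox_fit")
}

#' @export
print.index_cox_fit <- function(x, ...) {
  cat(sprintf("index_cox_fit [%s]\n", x$mode))
  print(x$results)
  invisible(x)
}

#' Predicted relapse-free survival curves from a discrete index model
#'
#' Baseline cumulative hazard is estimated from the fitted Cox model and
#' survival curves are predicted for every combination of index group and
#' node status. Curves start at probability 1 at time 0, are monotone
#' non-increasing, and are truncated at the requested horizon.
#'
#' @param model A discrete-mode [index_cox()] fit.
#' @param horizon Positive follow-up horizon in years.
#' @return Data frame `time`, `group` (`"low"`/`"high"`), `node`,
#'   `survival`.
#' @export
predict_survival_curves <- function(model, horizon = 10) {
  stopifnot(inherits(model, "index_cox_fit"))
  if (model$mode != "discrete")
    stop("survival curves are predicted from the discrete model")
  if (horizon <= 0) stop("horizon must be positive")
  node_levels <- if (model$adjusted_for_node) c(0, 1) else NA_real_
  grid <- expand.grid(index = c(0, 1), node = node_levels)
  newdata <- grid[, intersect(names(grid), c("index", "node")),
                  drop = FALSE]
  if (!model$adjusted_for_node) newdata$node <- NULL
  sf <- survival::survfit(model$fit, newdata = newdata)
  times <- c(0, sf$time[sf$time <= horizon])
  surv <- rbind(1, as.matrix(sf$surv)[sf$time <= horizon, , drop = FALSE])
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(j) {
    data.frame(time = times,
               group = ifelse(grid$index[j] == 1, "high", "low"),
               node = grid$node[j],
               survival = surv[, j],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
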