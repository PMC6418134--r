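#' Joint Cox proportional-hazards fit over several terms
#'
#' Fits one partial-likelihood Cox model (Efron tie handling) of recurrence
#' on the given gene-expression terms plus adjustment covariates, and
#' returns one result row per term. Samples missing the event, follow-up
#' time or any covariate are removed listwise; the count removed is stored
#' in the `n_excluded` column.
#'
#' Recognised covariate names: gene symbols present in the study's
#' expression matrix (continuous log2 expression) and `"node"`
#' (node-positive indicator).
#'
#' @param study A [cohort_study()].
#' @param terms Character vector of model terms to report (genes or
#'   `"node"`); must be unique and form a full-rank design together with
#'   `adjust`.
#' @param adjust Character vector of adjustment covariates (reported in the
#'   `covariates` column, not as rows). Default `"node"`.
#' @return A `cox_result` data frame: `term`, `B` (coefficient), `HR`
#'   (`exp(B)`), `p` (Wald), `ci_low`, `ci_high` (95% CI of HR),
#'   `covariates`, `n`, `n_events`, `n_excluded`, `converged`.
#' @export
multivariable_cox <- function(study, terms, adjust = "node") {
  if (!length(terms)) stop("no model terms given")
  if (anyDuplicated(terms)) stop("duplicated term(s): ",
                                 paste(unique(terms[duplicated(terms)]),
                                       collapse = ", "))
  all_terms <- c(terms, setdiff(adjust, terms))
  df <- model_frame(study, all_terms)
  n_total <- ncol(study$expression)
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  if (sum(df$.event) < 2L)
    stop("fewer than 2 events after listwise deletion")
  for (v in all_terms) {
    if (stats::sd(df[[make_term(v)]]) == 0)
      stop("zero-variance covariate: ", v)
  }
  x <- as.matrix(df[, make_term(all_terms), drop = FALSE])
  qrx <- qr(cbind(x))
  if (qrx$rank < ncol(x)) {
    dropped <- all_terms[qrx$pivot[(qrx$rank + 1L):ncol(x)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(make_term(all_terms), collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  summ <- summary(fit)
  co <- summ$coefficients
  ci <- summ$conf.int
  rows <- match(make_term(terms), rownames(co))
  out <- data.frame(term = terms,
                    B = unname(co[rows, "coef"]),
                    HR = unname(co[rows, "exp(coef)"]),
                    p = unname(co[rows, "Pr(>|z|)"]),
                    ci_low = unname(ci[rows, "lower .95"]),
                    ci_high = unname(ci[rows, "upper .95"]),
                    covariates = paste(setdiff(adjust, terms),
                                       collapse = "+"),
                    n = nrow(df),
                    n_events = sum(df$.event),
                    n_excluded = n_total - nrow(df),
                    converged = converged,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cox_result", "data.frame")
  out
}

# syntactically safe column names for gene symbols in formulas
make_term <- function(x) paste0("X", gsub("[^A-Za-z0-9]", "_", x))

# assemble the survival model frame for a set of covariate names
model_frame <- function(study, vars) {
  cl <- study$clinical
  df <- data.frame(.time = cl$followup_time,
                   .event = cl$recurrence_event)
  expr <- unclass(study$expression)
  for (v in vars) {
    col <- if (identical(v, "node")) cl$node_status
           else if (v %in% rownames(expr)) expr[v, ]
           else stop("unknown covariate: ", v,
                     " (not 'node' or a study gene)")
    df[[make_term(v)]] <- as.numeric(col)
  }
  df
}

#' Node-adjusted Cox fit for a single gene
#'
#' The per-gene screening model: recurrence hazard regressed on the gene's
#' continuous expression, adjusted for node status (or any covariate list).
#' Equivalent to [multivariable_cox()] with one term.
#'
#' @inheritParams multivariable_cox
#' @param gene Gene symbol.
#' @return One-row `cox_result` data frame (see [multivariable_cox()]).
#' @export
fit_cox_gene <- function(study, gene, adjust = "node") {
  stopifnot(length(gene) == 1L)
  multivariable_cox(study, terms = gene, adjust = adjust)
}

#' Screen a gene list with per-gene node-adjusted Cox models
#'
#' Runs [fit_cox_gene()] for every gene, preserving input order. A gene
#' whose fit fails (zero variance, too few events) yields a flagged row with
#' `NA` statistics and the error message in `note` rather than aborting the
#' screen. Significance stars follow the reporting convention: `*` for
#' p < 0.05, `**` for p < 0.01.
#'
#' @inheritParams multivariable_cox
#' @param genes Non-empty character vector of gene symbols.
#' @param fdr If `TRUE`, append a Benjamini-Hochberg adjusted p-value column
#'   `p_bh` (off by default; the screening convention reports raw p-values).
#' @return A `cox_result` data frame with one row per gene plus `stars` and
#'   `note` columns.
#' @export
screen_genes <- function(study, genes, adjust = "node", fdr = FALSE) {
  if (!length(genes)) stop("empty gene list")
  rows <- lapply(genes, function(g) {
    tryCatch(fit_cox_gene(study, g, adjust = adjust),
             error = function(e) {
               r <- data.frame(term = g, B = NA_real_, HR = NA_real_,
                               p = NA_real_, ci_low = NA_real_,
                               ci_high = NA_real_,
                               covariates = paste(adjust, collapse = "+"),
                               n = NA_integer_, n_events = NA_integer_,
                               n_excluded = NA_integer_, converged = FALSE,
                               stringsAsFactors = FALSE)
               attr(r, "note") <- conditionMessage(e)
               r
             })
  })
  notes <- vapply(rows, function(r) attr(r, "note") %||% "", character(1))
  out <- do.call(rbind, rows)
  out$stars <- significance_stars(out$p)
  out$note <- notes
  if (fdr) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("cox_result", "data.frame")
  out
}

#' Significance stars at the 0.05 / 0.01 convention
#'
#' @param p Numeric vector of p-values.
#' @return Character vector: `"**"` for p < 0.01, `"*"` for p < 0.05,
#'   otherwise `""` (`NA` p gives `""`).
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Logistic regression of node status on a gene's expression
#'
#' Maximum-likelihood logistic fit of the node-positive indicator on the
#' gene's continuous expression, summarising the association as an odds
#' ratio with a Wald 95% CI. Quasi-complete separation is flagged
#' (`converged = FALSE`) rather than raised.
#'
#' @inheritParams fit_cox_gene
#' @return One-row data frame: `term`, `OR`, `B`, `p`, `ci_low`, `ci_high`,
#'   `n`, `converged`.
#' @export
fit_logistic_node <- function(study, gene) {
  stopifnot(length(gene) == 1L)
  expr <- unclass(study$expression)
  if (!gene %in% rownames(expr)) stop("unknown gene: ", gene)
  df <- data.frame(node = study$clinical$node_status, x = expr[gene, ])
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (length(unique(df$node)) < 2L)
    stop("only one node-status class present")
  if (stats::sd(df$x) == 0) stop("zero-variance gene: ", gene)
  flagged <- FALSE
  fit <- withCallingHandlers(
    stats::glm(node ~ x, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge",
                conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  co <- summary(fit)$coefficients
  b <- co["x", "Estimate"]
  se <- co["x", "Std. Error"]
  data.frame(term = gene, OR = exp(b), B = b, p = co["x", "Pr(>|z|)"],
             ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
             n = nrow(df), converged = !flagged,
             stringsAsFactors = FALSE)
}
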