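#' Expression matrix constructor
#'
#' A thin wrapper around a numeric genes-by-samples matrix carrying the cohort
#' label and the measurement level. Probe-level matrices may contain repeated
#' row identifiers (several probes per gene); gene-level matrices must not.
#'
#' @param values Numeric matrix, genes (rows) by samples (columns), with
#'   row and column names set. Values are expected on the log2 intensity
#'   scale unless the matrix is about to be harmonized from a declared
#'   linear scale.
#' @param cohort Single cohort label.
#' @param scale_tag Either `"gene_level"` or `"probe_level"`.
#' @return An `expr_matrix`: the input matrix with `cohort` and `scale_tag`
#'   attributes.
#' @export
expr_matrix <- function(values, cohort = "cohort", scale_tag = "gene_level") {
  scale_tag <- match.arg(scale_tag, c("gene_level", "probe_level"))
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs row (gene/probe) and column (sample) names")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (scale_tag == "gene_level" && anyDuplicated(rownames(values)))
    stop("duplicate gene IDs in a gene-level matrix: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  structure(values, cohort = cohort, scale_tag = scale_tag,
            class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s, %s]: %d features x %d samples\n",
              attr(x, "cohort"), attr(x, "scale_tag"), nrow(x), ncol(x)))
  invisible(x)
}

scale_tag <- function(m) attr(m, "scale_tag") %||% "gene_level"
cohort_label <- function(m) attr(m, "cohort") %||% "cohort"
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bind an expression matrix to its clinical table
#'
#' The universal pipeline input: a gene-level expression matrix together with
#' one clinical record per sample. Samples are matched by ID and the clinical
#' table is reordered to the expression column order; any mismatch between
#' the two sample sets is an error.
#'
#' Clinical columns: `sample_id`, `recurrence_event` (0/1 or `NA`),
#' `followup_time` (years, strictly positive), `node_status` (0/1 or `NA`),
#' `cohort`. Records with missing `recurrence_event` stay in the expression
#' matrix but are excluded from every survival fit downstream.
#'
#' @param expression A gene-level [expr_matrix()] (a plain named matrix is
#'   accepted and tagged gene-level).
#' @param clinical Data frame with the columns listed above (`cohort` is
#'   filled from the expression matrix when absent).
#' @param provenance Character vector of source cohort labels.
#' @return A `cohort_study` object (list with `expression`, `clinical`,
#'   `provenance`).
#' @export
cohort_study <- function(expression, clinical,
                         provenance = cohort_label(expression)) {
  if (!inherits(expression, "expr_matrix"))
    expression <- expr_matrix(expression)
  if (scale_tag(expression) != "gene_level")
    stop("a cohort_study requires a gene-level expression matrix; ",
         "collapse probes first")
  clinical <- as.data.frame(clinical, stringsAsFactors = FALSE)
  needed <- c("sample_id", "recurrence_event", "followup_time", "node_status")
  missing_cols <- setdiff(needed, names(clinical))
  if (length(missing_cols))
    stop("clinical table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"cohort" %in% names(clinical))
    clinical$cohort <- cohort_label(expression)
  if (anyDuplicated(clinical$sample_id))
    stop("duplicate sample IDs in clinical table")
  if (!setequal(clinical$sample_id, colnames(expression)))
    stop("expression and clinical sample sets differ (",
         length(setdiff(colnames(expression), clinical$sample_id)),
         " expression-only, ",
         length(setdiff(clinical$sample_id, colnames(expression))),
         " clinical-only)")
  clinical <- clinical[match(colnames(expression), clinical$sample_id), ,
                       drop = FALSE]
  rownames(clinical) <- NULL
  bad_t <- !is.na(clinical$followup_time) & clinical$followup_time <= 0
  if (any(bad_t))
    stop("non-positive follow-up time for sample(s): ",
         paste(utils::head(clinical$sample_id[bad_t], 5), collapse = ", "))
  structure(list(expression = expression, clinical = clinical,
                 provenance = provenance),
            class = "cohort_study")
}

#' @export
print.cohort_study <- function(x, ...) {
  ev <- x$clinical$recurrence_event
  cat(sprintf(
    "cohort_study: %d genes x %d samples [%s]\n  events %d / missing %d; node+ %d / node- %d / missing %d\n",
    nrow(x$expression), ncol(x$expression),
    paste(x$provenance, collapse = "+"),
    sum(ev == 1, na.rm = TRUE), sum(is.na(ev)),
    sum(x$clinical$node_status == 1, na.rm = TRUE),
    sum(x$clinical$node_status == 0, na.rm = TRUE),
    sum(is.na(x$clinical$node_status))))
  invisible(x)
}

#' @export
dim.cohort_study <- function(x) dim(x$expression)

#' Read a delimited expression table
#'
#' Parses a GEO-series-matrix-like layout: first column feature (gene or
#' probe) IDs, header row sample IDs, numeric cells. The delimiter is
#' sniffed from the header (tab preferred over comma) unless given.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` (default) sniffs tab then comma.
#' @param cohort Cohort label to attach.
#' @param scale_tag `"gene_level"` or `"probe_level"`; probe-level tables may
#'   repeat feature IDs.
#' @return An [expr_matrix()].
#' @export
read_expression_table <- function(path, sep = NULL, cohort = "cohort",
                                  scale_tag = "gene_level") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2L) stop("expression table needs an ID column plus samples")
  ids <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample IDs in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow(raw), length(samples),
                 dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- is.na(num) & !(is.na(col) | col %in% c("NA", ""))
    if (any(bad))
      stop(sprintf("unparsable cell at row '%s', column '%s': '%s'",
                   ids[which(bad)[1L]], samples[j], col[which(bad)[1L]]))
    vals[, j] <- num
  }
  if (anyNA(vals))
    stop("missing expression cells are not supported (first at row '",
         ids[which(rowSums(is.na(vals)) > 0)[1L]], "')")
  expr_matrix(vals, cohort = cohort, scale_tag = scale_tag)
}

#' Read a clinical table
#'
#' TSV/CSV with columns `sample_id`, `recurrence_event`, `followup_time`,
#' `node_status` and optionally `cohort`. Empty cells and `NA` become missing.
#'
#' @inheritParams read_expression_table
#' @return A data frame suitable for [cohort_study()].
#' @export
read_clinical_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  cl <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  needed <- c("sample_id", "recurrence_event", "followup_time", "node_status")
  miss <- setdiff(needed, names(cl))
  if (length(miss))
    stop("clinical table lacks column(s): ", paste(miss, collapse = ", "))
  cl$sample_id <- as.character(cl$sample_id)
  for (col in c("recurrence_event", "followup_time", "node_status"))
    cl[[col]] <- as.numeric(cl[[col]])
  bad <- !is.na(cl$recurrence_event) & !cl$recurrence_event %in% c(0, 1)
  if (any(bad)) stop("recurrence_event must be 0/1/missing")
  bad <- !is.na(cl$node_status) & !cl$node_status %in% c(0, 1)
  if (any(bad)) stop("node_status must be 0/1/missing")
  cl
}

#' Collapse probe-level rows to one row per gene
#'
#' Microarray platforms measure most genes with several probes; the
#' per-sample median across a gene's probes represents the gene. Probes
#' without a mapping entry are dropped (a message reports the count).
#'
#' @param m Probe-level [expr_matrix()].
#' @param probe_to_gene Two-column data frame (`probe_id`, `gene_symbol`) or
#'   a named character vector `probe -> symbol`. Each retained probe must map
#'   to exactly one symbol.
#' @return A gene-level [expr_matrix()], genes in alphabetical order.
#' @export
collapse_probes <- function(m, probe_to_gene) {
  if (scale_tag(m) != "probe_level")
    stop("`m` must be a probe-level expr_matrix")
  if (is.data.frame(probe_to_gene)) {
    if (ncol(probe_to_gene) < 2L) stop("probe map needs two columns")
    map <- stats::setNames(as.character(probe_to_gene[[2L]]),
                           as.character(probe_to_gene[[1L]]))
  } else {
    map <- probe_to_gene
  }
  map <- map[!is.na(map) & nzchar(map)]
  if (!length(map)) stop("empty probe-to-gene mapping")
  if (anyDuplicated(names(map))) {
    amb <- unique(names(map)[duplicated(names(map))])
    keep <- !duplicated(names(map))
    one <- map[keep]
    conflicting <- vapply(amb, function(p)
      length(unique(map[names(map) == p])) > 1L, logical(1))
    if (any(conflicting))
      stop("probe(s) mapped to more than one gene: ",
           paste(amb[conflicting], collapse = ", "))
    map <- one
  }
  probes <- rownames(m)
  mapped <- probes %in% names(map)
  if (sum(!mapped))
    message(sum(!mapped), " unmapped probe(s) dropped")
  if (!any(mapped)) stop("no probe in the matrix is covered by the mapping")
  sub <- m[mapped, , drop = FALSE]
  genes <- unname(map[rownames(sub)])
  idx <- split(seq_len(nrow(sub)), genes)      # alphabetical by gene
  out <- matrix(NA_real_, length(idx), ncol(m),
                dimnames = list(names(idx), colnames(m)))
  for (k in seq_along(idx)) {
    rows <- idx[[k]]
    out[k, ] <- if (length(rows) == 1L) sub[rows, ]
                else apply(sub[rows, , drop = FALSE], 2L, stats::median)
  }
  expr_matrix(out, cohort = cohort_label(m), scale_tag = "gene_level")
}

#' Pooled distribution moments of an expression matrix
#'
#' Mean, standard deviation, skewness and excess-free (Pearson) kurtosis of
#' all matrix entries pooled, used as harmonization diagnostics.
#'
#' @param m Numeric matrix.
#' @return Named numeric vector `mean`, `sd`, `skewness`, `kurtosis`.
#' @export
pooled_moments <- function(m) {
  x <- as.numeric(m)
  mu <- mean(x)
  s <- stats::sd(x)
  z <- (x - mu) / s
  c(mean = mu, sd = s,
    skewness = mean(z^3),
    kurtosis = mean(z^4))
}

#' Align a cohort's expression distribution to a reference cohort
#'
#' Non-reference cohorts are put on the log2 scale (if declared linear) and
#' then linearly mapped so the pooled distribution's mean and standard
#' deviation match the reference's. A single global linear map matches the
#' first two moments exactly; skewness and kurtosis cannot be set by a linear
#' map and are reported as diagnostics instead (attribute `"moments"`, with
#' before/after/reference rows).
#'
#' @param target Gene-level [expr_matrix()] to align.
#' @param reference Gene-level [expr_matrix()] providing the target moments.
#' @param target_scale `"log2"` (default) or `"linear"`; linear targets are
#'   log2-transformed first and must be strictly positive.
#' @return The aligned [expr_matrix()]; attribute `"moments"` carries the
#'   diagnostic table.
#' @export
harmonize_to_reference <- function(target, reference,
                                   target_scale = c("log2", "linear")) {
  target_scale <- match.arg(target_scale)
  for (m in list(target, reference))
    if (scale_tag(m) != "gene_level")
      stop("harmonization operates on gene-level matrices")
  x <- unclass(target)
  if (target_scale == "linear") {
    if (any(x <= 0))
      stop("non-positive values in a declared-linear matrix cannot be ",
           "log2-transformed")
    x <- log2(x)
  }
  before <- pooled_moments(x)
  if (before[["sd"]] < .Machine$double.eps^0.5)
    stop("zero-variance target matrix cannot be aligned")
  ref <- pooled_moments(reference)
  y <- (x - before[["mean"]]) / before[["sd"]] * ref[["sd"]] + ref[["mean"]]
  out <- expr_matrix(y, cohort = cohort_label(target),
                     scale_tag = "gene_level")
  attr(out, "moments") <- rbind(before = before,
                                after = pooled_moments(y),
                                reference = ref)
  out
}

#' Merge harmonized cohorts into one study
#'
#' Restricts every cohort to the common gene set (their intersection),
#' concatenates samples, and stacks the clinical tables. Cohort labels are
#' recorded in `provenance`.
#'
#' @param studies List of [cohort_study()] objects (length >= 1), already
#'   harmonized to a common reference.
#' @return One merged [cohort_study()].
#' @export
merge_cohorts <- function(studies) {
  if (!length(studies)) stop("need at least one study")
  if (!all(vapply(studies, inherits, logical(1), "cohort_study")))
    stop("`studies` must be a list of cohort_study objects")
  if (length(studies) == 1L) return(studies[[1L]])
  gene_sets <- lapply(studies, function(s) rownames(s$expression))
  genes <- Reduce(intersect, gene_sets)
  if (!length(genes)) stop("empty gene intersection across cohorts")
  all_samples <- unlist(lapply(studies, function(s) colnames(s$expression)))
  if (anyDuplicated(all_samples))
    stop("sample ID collision across cohorts: ",
         paste(utils::head(unique(all_samples[duplicated(all_samples)]), 5),
               collapse = ", "))
  expr <- do.call(cbind, lapply(studies, function(s)
    unclass(s$expression)[genes, , drop = FALSE]))
  clin <- do.call(rbind, lapply(studies, function(s) s$clinical))
  rownames(clin) <- NULL
  prov <- unlist(lapply(studies, function(s) s$provenance))
  cohort_study(expr_matrix(expr, cohort = paste(prov, collapse = "+")),
               clin, provenance = prov)
}

#' Write a cohort study to plain-text tables
#'
#' @param study A [cohort_study()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the two file paths written (`expression.tsv`,
#'   `clinical.tsv` under `prefix_`).
#' @export
write_cohort_tsv <- function(study, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ep <- file.path(dir, paste0(prefix, "_expression.tsv"))
  cp <- file.path(dir, paste0(prefix, "_clinical.tsv"))
  df <- data.frame(gene = rownames(study$expression),
                   unclass(study$expression), check.names = FALSE)
  utils::write.table(df, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$clinical, cp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expression = ep, clinical = cp))
}
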