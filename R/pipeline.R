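#' End-to-end pipeline configuration
#'
#' Exactly one input source must be given: either file paths (`expression`,
#' `clinical`, one per cohort, with optional `probe_map` and per-cohort
#' scale declarations) or a [sim_config()]. The remaining fields control
#' the analysis stages.
#'
#' @param input Named list of file paths: `expression` (character vector,
#'   one table per cohort), `clinical` (same length), optional `probe_map`
#'   (two-column TSV), optional `scale` (per-cohort `"log2"`/`"linear"`,
#'   recycled). The first cohort is the harmonization reference.
#' @param simulation A [sim_config()] generating the study instead.
#' @param seeds Seed-gene symbols; defaults to the simulation's seed list
#'   when simulating.
#' @param threshold,edge_limit,absolute,cut,strata,min_samples Network
#'   construction settings (see [build_stratum_networks()]).
#' @param index_genes Either `"discover"` (use the novel genes surfaced by
#'   the networks and screen) or an explicit gene vector for the index.
#' @param percentile Index dichotomization percentile.
#' @param out_dir Output directory for the report bundle.
#' @param rng_seed Integer seed controlling every random draw.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL, seeds = NULL,
                            threshold = 0.9, edge_limit = 1L,
                            absolute = FALSE, cut = c("max", "total"),
                            strata = c("recurrence", "node"),
                            min_samples = 20L,
                            index_genes = "discover", percentile = 40,
                            out_dir = "recoex_out", rng_seed = 1L) {
  cut <- match.arg(cut)
  if (is.null(input) == is.null(simulation))
    stop("give exactly one of `input` (file paths) or `simulation`")
  if (!is.null(simulation)) stopifnot(inherits(simulation, "sim_config"))
  if (!is.null(input)) {
    if (is.null(input$expression) || is.null(input$clinical))
      stop("`input` needs $expression and $clinical paths")
    paths <- c(input$expression, input$clinical, input$probe_map)
    absent <- paths[!file.exists(paths)]
    if (length(absent)) stop("missing input file(s): ",
                             paste(absent, collapse = ", "))
    if (is.null(seeds)) stop("`seeds` is required with file input")
  }
  if (is.null(seeds)) seeds <- simulation$seed_genes
  structure(list(input = input, simulation = simulation, seeds = seeds,
                 threshold = threshold, edge_limit = edge_limit,
                 absolute = absolute, cut = cut, strata = strata,
                 min_samples = min_samples, index_genes = index_genes,
                 percentile = percentile, out_dir = out_dir,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: load-or-simulate, harmonize non-reference cohorts, merge,
#' per-stratum network construction, pairwise network comparison, Cox
#' screen of all network genes, immune-index construction, continuous and
#' discrete index models, and predicted survival curves. Every table is
#' written under `cfg$out_dir` and a JSON manifest records the seed,
#' per-stage row counts and exclusions. Identical config + seed yields an
#' identical bundle. A stage failure aborts with the stage name after
#' writing the partial manifest.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with `study`, `networks`, `comparisons`,
#'   `screen`, `novel_genes`, `index`, `models`, `curves`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(rng_seed = cfg$rng_seed,
                   package_version = as.character(
                     utils::packageVersion("recoex")),
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <- list(status = "failed",
                                      error = conditionMessage(e))
      jsonlite::write_json(manifest,
                           file.path(cfg$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  set.seed(cfg$rng_seed)
  study <- stage("load", {
    if (!is.null(cfg$simulation)) {
      sim <- cfg$simulation
      sim$rng_seed <- cfg$rng_seed
      simulate_study(sim)
    } else {
      n_c <- length(cfg$input$expression)
      scl <- rep(cfg$input$scale %||% "log2", length.out = n_c)
      studies <- lapply(seq_len(n_c), function(i) {
        m <- read_expression_table(cfg$input$expression[i],
                                   cohort = paste0("cohort", i),
                                   scale_tag = if (is.null(cfg$input$probe_map))
                                     "gene_level" else "probe_level")
        if (!is.null(cfg$input$probe_map)) {
          pm <- utils::read.table(cfg$input$probe_map, sep = "\t",
                                  header = TRUE, stringsAsFactors = FALSE)
          m <- collapse_probes(m, pm)
        }
        cl <- read_clinical_table(cfg$input$clinical[i])
        cohort_study(m, cl, provenance = paste0("cohort", i))
      })
      ref <- studies[[1L]]$expression
      studies <- lapply(seq_along(studies), function(i) {
        if (i == 1L) return(studies[[i]])
        s <- studies[[i]]
        cohort_study(harmonize_to_reference(s$expression, ref,
                                            target_scale = scl[i]),
                     s$clinical, provenance = s$provenance)
      })
      merge_cohorts(studies)
    }
  })
  manifest$stages$load <- list(
    status = "ok", genes = nrow(study$expression),
    samples = ncol(study$expression),
    events = sum(study$clinical$recurrence_event == 1, na.rm = TRUE),
    missing_event = sum(is.na(study$clinical$recurrence_event)),
    missing_node = sum(is.na(study$clinical$node_status)))
  write_cohort_tsv(study, cfg$out_dir, prefix = "merged")

  networks <- stage("networks",
    build_stratum_networks(study, cfg$seeds, strata = cfg$strata,
                           threshold = cfg$threshold,
                           edge_limit = cfg$edge_limit,
                           absolute = cfg$absolute, cut = cfg$cut,
                           min_samples = cfg$min_samples))
  manifest$stages$networks <- list(
    status = "ok",
    strata = lapply(networks, function(nw)
      list(nodes = nrow(nw$nodes), edges = nrow(nw$edges),
           samples = length(nw$samples))))
  for (nm in names(networks)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", nm)
    export_network(networks[[nm]],
                   file.path(cfg$out_dir,
                             paste0("network_", safe, ".graphml")),
                   format = "graphml")
    export_network(networks[[nm]],
                   file.path(cfg$out_dir, paste0("network_", safe, ".json")),
                   format = "json")
  }

  comparisons <- stage("compare", {
    nms <- names(networks)
    pairs <- if (length(nms) < 2L) list() else utils::combn(nms, 2L,
                                                            simplify = FALSE)
    out <- lapply(pairs, function(p)
      compare_networks(networks[[p[1L]]], networks[[p[2L]]]))
    names(out) <- vapply(pairs, paste, character(1), collapse = " vs ")
    out
  })
  manifest$stages$compare <- list(status = "ok",
                                  n_pairs = length(comparisons))
  jsonlite::write_json(
    lapply(comparisons, unclass),
    file.path(cfg$out_dir, "network_comparisons.json"),
    auto_unbox = TRUE, pretty = TRUE)

  screen <- stage("screen", {
    coexpressed <- sort(unique(unlist(lapply(networks, function(nw)
      nw$nodes$gene[!nw$nodes$is_seed]))))
    if (!length(coexpressed))
      stop("no co-expressed genes survived edge selection")
    screen_genes(study, coexpressed)
  })
  manifest$stages$screen <- list(status = "ok", genes = nrow(screen),
                                 significant = sum(screen$p < 0.05,
                                                   na.rm = TRUE))
  write_results_tables(list(gene_screen = screen), cfg$out_dir)

  novel <- stage("novel_genes", {
    counts <- table(unlist(lapply(networks, function(nw)
      unique(nw$nodes$gene[!nw$nodes$is_seed]))))
    sig <- screen$term[!is.na(screen$p) & screen$p < 0.05]
    sort(intersect(names(counts), sig))
  })
  manifest$stages$novel_genes <- list(status = "ok", genes = novel)

  index_set <- stage("index_genes", {
    if (identical(cfg$index_genes, "discover")) {
      if (length(novel) < 2L)
        stop("fewer than 2 novel genes discovered; supply `index_genes` ",
             "explicitly")
      novel
    } else cfg$index_genes
  })

  index <- stage("index", {
    idx <- compute_immune_index(study, index_set)
    dichotomize_index(idx, percentile = cfg$percentile)
  })
  manifest$stages$index <- list(
    status = "ok", genes = index_set,
    explained_variance = index$explained_variance_fraction,
    cutoff_value = index$cutoff_value,
    n_low = sum(index$group == "low"),
    n_high = sum(index$group == "high"))
  utils::write.table(
    data.frame(sample_id = names(index$sample_scores),
               score = as.numeric(index$sample_scores),
               group = as.character(index$group[names(index$sample_scores)]),
               stringsAsFactors = FALSE),
    file.path(cfg$out_dir, "immune_index.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = names(index$loadings),
               loading = as.numeric(index$loadings)),
    file.path(cfg$out_dir, "index_loadings.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  models <- stage("models", list(
    continuous = index_cox(study, index, mode = "continuous"),
    discrete = index_cox(study, index, mode = "discrete")))
  write_results_tables(list(index_model_continuous = models$continuous$results,
                            index_model_discrete = models$discrete$results),
                       cfg$out_dir)
  manifest$stages$models <- list(
    status = "ok",
    continuous_hr = models$continuous$results$HR[1L],
    continuous_p = models$continuous$results$p[1L],
    discrete_hr = models$discrete$results$HR[1L],
    discrete_p = models$discrete$results$p[1L])

  curves <- stage("curves",
    predict_survival_curves(models$discrete, horizon = 10))
  utils::write.table(curves, file.path(cfg$out_dir, "survival_curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$curves <- list(status = "ok", rows = nrow(curves))

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(study = study, networks = networks,
                 comparisons = comparisons, screen = screen,
                 novel_genes = novel, index = index, models = models,
                 curves = curves, manifest = manifest))
}

#' Export a network to GraphML or JSON node-link format
#'
#' Both formats carry every node attribute (`is_seed`, `cv`, `cox_p`,
#' `cluster`, `shape`, `frame`, `direction`) and the edge weights, with
#' nodes and edges in deterministic (alphabetical) order, so re-exporting
#' an imported network reproduces the file byte for byte.
#'
#' @param network A `gene_network`.
#' @param path Output file path.
#' @param format `"graphml"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(network, path, format = c("graphml", "json")) {
  format <- match.arg(format)
  nodes <- network$nodes[order(network$nodes$gene), , drop = FALSE]
  edges <- network$edges[order(network$edges$gene_a,
                               network$edges$gene_b), , drop = FALSE]
  if (format == "json") {
    payload <- list(
      stratum = network$stratum,
      threshold = network$threshold,
      edge_limit = network$edge_limit,
      nodes = nodes, links = edges)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, dataframe = "rows")
    return(invisible(path))
  }
  num <- function(x) sprintf("%.17g", x)
  esc <- function(x) gsub("&", "&amp;",
                          gsub("<", "&lt;", gsub(">", "&gt;", x)))
  keys <- c(
    '  <key id="is_seed" for="node" attr.name="is_seed" attr.type="boolean"/>',
    '  <key id="cv" for="node" attr.name="cv" attr.type="double"/>',
    '  <key id="cox_p" for="node" attr.name="cox_p" attr.type="double"/>',
    '  <key id="cluster" for="node" attr.name="cluster" attr.type="long"/>',
    '  <key id="shape" for="node" attr.name="shape" attr.type="string"/>',
    '  <key id="frame" for="node" attr.name="frame" attr.type="string"/>',
    '  <key id="direction" for="node" attr.name="direction" attr.type="string"/>',
    '  <key id="weight" for="edge" attr.name="weight" attr.type="double"/>',
    '  <key id="stratum" for="graph" attr.name="stratum" attr.type="string"/>')
  node_xml <- vapply(seq_len(nrow(nodes)), function(i) {
    n <- nodes[i, ]
    paste0('    <node id="', esc(n$gene), '">\n',
           '      <data key="is_seed">', tolower(as.character(n$is_seed)),
           '</data>\n',
           '      <data key="cv">', num(n$cv), '</data>\n',
           if (!is.na(n$cox_p))
             paste0('      <data key="cox_p">', num(n$cox_p), '</data>\n')
           else "",
           '      <data key="cluster">', n$cluster, '</data>\n',
           '      <data key="shape">', n$shape, '</data>\n',
           '      <data key="frame">', n$frame, '</data>\n',
           '      <data key="direction">', n$direction, '</data>\n',
           '    </node>')
  }, character(1))
  edge_xml <- vapply(seq_len(nrow(edges)), function(i) {
    e <- edges[i, ]
    paste0('    <edge source="', esc(e$gene_a), '" target="',
           esc(e$gene_b), '">\n',
           '      <data key="weight">', num(e$rho), '</data>\n',
           '    </edge>')
  }, character(1))
  xml <- c('<?xml version="1.0" encoding="UTF-8"?>',
           '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
           keys,
           '  <graph id="G" edgedefault="undirected">',
           paste0('    <data key="stratum">', esc(network$stratum),
                  '</data>'),
           node_xml, edge_xml,
           '  </graph>', '</graphml>')
  writeLines(xml, path)
  invisible(path)
}

#' Import a network written by [export_network()]
#'
#' GraphML files are parsed with igraph; JSON node-link files with
#' jsonlite. Node and edge attributes are restored exactly.
#'
#' @param path File path.
#' @param format `"graphml"` or `"json"`; guessed from the extension when
#'   missing.
#' @return A `gene_network` (without the sample list, which export does not
#'   carry).
#' @export
import_network <- function(path, format = c("guess", "graphml", "json")) {
  format <- match.arg(format)
  if (format == "guess")
    format <- if (grepl("\\.json$", path)) "json" else "graphml"
  if (format == "json") {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- as.data.frame(payload$nodes, stringsAsFactors = FALSE)
    edges <- as.data.frame(payload$links, stringsAsFactors = FALSE)
    if (!nrow(nodes))
      nodes <- data.frame(gene = character(0), is_seed = logical(0),
                          cluster = integer(0), cv = numeric(0),
                          cox_p = numeric(0), shape = character(0),
                          frame = character(0), direction = character(0))
    if (!nrow(edges))
      edges <- data.frame(gene_a = character(0), gene_b = character(0),
                          rho = numeric(0))
    return(structure(list(nodes = nodes, edges = edges,
                          stratum = payload$stratum, samples = NULL,
                          threshold = payload$threshold,
                          edge_limit = payload$edge_limit),
                     class = "gene_network"))
  }
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::vcount(g)) {
    va <- igraph::vertex_attr(g)
    cox_p <- if (is.null(va$cox_p)) rep(NA_real_, igraph::vcount(g))
             else as.numeric(va$cox_p)
    cox_p[is.nan(cox_p)] <- NA_real_   # igraph encodes absent doubles as NaN
    nodes <- data.frame(gene = va$id, is_seed = as.logical(va$is_seed),
                        cv = as.numeric(va$cv), cox_p = cox_p,
                        cluster = as.integer(va$cluster),
                        shape = va$shape, frame = va$frame,
                        direction = va$direction,
                        stringsAsFactors = FALSE)
  } else {
    nodes <- data.frame(gene = character(0), is_seed = logical(0),
                        cv = numeric(0), cox_p = numeric(0),
                        cluster = integer(0), shape = character(0),
                        frame = character(0), direction = character(0))
  }
  ids <- if (igraph::vcount(g)) igraph::vertex_attr(g, "id") else character(0)
  el <- igraph::as_edgelist(g, names = FALSE)
  ga <- ids[el[, 1L]]
  gb <- ids[el[, 2L]]
  # GraphML stores undirected edges; restore the seed-first orientation
  # (alphabetical within seed-seed pairs, as built)
  seed_of <- stats::setNames(nodes$is_seed, nodes$gene)
  for (i in seq_along(ga)) {
    a_seed <- isTRUE(seed_of[[ga[i]]])
    b_seed <- isTRUE(seed_of[[gb[i]]])
    flip <- (b_seed && !a_seed) || (a_seed == b_seed && gb[i] < ga[i])
    if (flip) {
      tmp <- ga[i]; ga[i] <- gb[i]; gb[i] <- tmp
    }
  }
  edges <- data.frame(gene_a = ga, gene_b = gb,
                      rho = if (igraph::ecount(g))
                        igraph::edge_attr(g, "weight") else numeric(0),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$gene), , drop = FALSE]
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 stratum = igraph::graph_attr(g, "stratum") %||% "imported",
                 samples = NULL, threshold = NA_real_,
                 edge_limit = NA_integer_),
            class = "gene_network")
}

#' Write result tables as TSV with significance stars
#'
#' Each element of `results` is written as `<name>.tsv` under `out_dir`,
#' with a `stars` column added to any table carrying a `p` column (`*` for
#' p < 0.05, `**` for p < 0.01) and a stable column order.
#'
#' @param results Named list of data frames.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_results_tables <- function(results, out_dir) {
  if (!length(results) || is.null(names(results)))
    stop("`results` must be a non-empty named list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, mode = 2L) != 0L)
    stop("output directory not writable: ", out_dir)
  paths <- vapply(names(results), function(nm) {
    df <- as.data.frame(results[[nm]])
    if ("p" %in% names(df) && !"stars" %in% names(df))
      df$stars <- significance_stars(df$p)
    lead <- intersect(c("term", "B", "HR", "p", "stars",
                        "ci_low", "ci_high"), names(df))
    df <- df[, c(lead, setdiff(names(df), lead)), drop = FALSE]
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
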