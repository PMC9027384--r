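#' Run the full transcriptional-network response pipeline
#'
#' Orchestrates every stage end to end: DEG filtering, profile scaling,
#' must-link constraint derivation from TF/SF background knowledge,
#' silhouette-selected constrained k-means, GO and TF/SF over-representation
#' analysis, selection of important combinations, the co-regulation level
#' hierarchy with per-timepoint t-tests, and all exports. A JSON run
#' manifest records the configuration, input/output checksums, derived
#' seeds and stage timings; re-running with the same inputs and seed
#' reproduces every output byte for byte.
#'
#' @param expression Path to an expression matrix file, or a matrix from
#'   [read_expression()].
#' @param network Path to a TF/SF interaction table, or a data.frame from
#'   [read_network()].
#' @param go Optional path to a two-column gene/GO-category table, or an
#'   equivalent data.frame; `NULL` skips the GO stage.
#' @param config A [pipeline_config()].
#' @param outdir Output directory; `NULL` skips all file output.
#' @return Invisibly, a list: `config`, `deg`, `scaled`, `constraints`,
#'   `clusters`, `enrich_go`, `enrich_tfsf`, `important`, `groups`,
#'   `ttests`, `manifest`.
#' @export
run_pipeline <- function(expression, network, go = NULL,
                         config = pipeline_config(), outdir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  input_paths <- c(
    expression = if (is.character(expression)) expression,
    network = if (is.character(network)) network,
    go = if (is.character(go)) go
  )
  for (p in input_paths) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }

  x <- if (is.character(expression)) read_expression(expression) else expression
  interactions <- if (is.character(network)) read_network(network) else network
  go_tab <- if (is.character(go)) {
    utils::read.table(go, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE)
  } else go
  tick("read")

  message("DEG filter: |log2FC| >= ", config$deg_threshold)
  deg <- filter_degs(x, config$deg_threshold)
  message("  ", length(deg$gene_ids), " / ", nrow(x), " genes differential")
  scaled <- scale_profiles(x, deg)
  tick("filter")

  signatures <- build_signatures(interactions, rownames(x))
  combo_index <- build_combination_index(signatures)
  constraints <- derive_mustlinks(signatures, deg, config$max_pairs)
  message("constraints: ", nrow(constraints$must_links), " must-link pair(s)")
  tick("constraints")

  message("cluster search: k in ", config$k_min, "..", config$k_max,
          ", ", config$repeats_per_k, " restarts per k, seed ", config$seed)
  clusters <- select_k(scaled, constraints, config)
  message("  selected k = ", clusters$k,
          sprintf(" (mean silhouette %.3f)", clusters$silhouette))
  tick("clustering")

  tfsf_universe <- switch(config$universe,
    annotation = intersect(rownames(x), unique(interactions$gene)),
    array = rownames(x))
  enrich_tfsf <- enrich_clusters(clusters, combo_index, tfsf_universe, config)
  enrich_go <- NULL
  if (!is.null(go_tab)) {
    go_universe <- switch(config$universe,
      annotation = intersect(rownames(x), unique(as.character(go_tab[[1L]]))),
      array = rownames(x))
    enrich_go <- enrich_clusters(clusters, go_tab, go_universe, config)
  }
  important <- select_important(enrich_tfsf)
  message("important TF/SF combinations (>= ", config$min_genes,
          " genes, corrected p < ", config$alpha_enrich, "): ",
          length(important))
  tick("enrichment")

  groups <- structure(list(), class = "level_groups")
  ttests <- NULL
  if (length(important) > 0L) {
    lev <- coregulation_analysis(deg, important, signatures, x, config)
    groups <- lev$groups
    ttests <- lev$ttests
    message("level analysis: ", length(groups), " group(s), ",
            sum(vapply(groups, `[[`, logical(1L), "decisive")), " decisive",
            " (alpha ", config$alpha_level, ")")
  } else {
    message("no important combinations; level analysis skipped")
  }
  tick("levels")

  manifest <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(outdir, f)
    write_clusters(clusters, out("assignments.tsv"), out("silhouette.tsv"))
    wt <- function(df, f) utils::write.table(df, out(f), sep = "\t",
                                             quote = FALSE, row.names = FALSE)
    wt(enrich_tfsf, "enrichment_tfsf.tsv")
    if (!is.null(enrich_go)) {
      wt(enrich_go, "enrichment_go.tsv")
      export_revigo(enrich_go, out("revigo.txt"))
    }
    wt(data.frame(combination = important), "important.tsv")
    if (length(groups) > 0L) {
      wt(as.data.frame(groups), "levels.tsv")
      wt(ttests, "ttests.tsv")
      export_heatmap(ttests, out("heatmap.tsv"))
    }
    outputs <- list.files(outdir, full.names = TRUE)
    outputs <- outputs[basename(outputs) != "manifest.json"]
    manifest <- list(
      config = unclass(config),
      inputs = as.list(if (length(input_paths)) tools::md5sum(input_paths) else c()),
      outputs = as.list(tools::md5sum(outputs)),
      seeds = list(master = config$seed),
      timings_s = as.list(timings),
      finished = format(Sys.time(), tz = "UTC", usetz = TRUE)
    )
    # atomic write: manifest appears complete or not at all
    tmp <- tempfile(tmpdir = outdir)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    file.rename(tmp, file.path(outdir, "manifest.json"))
  }

  invisible(list(config = config, deg = deg, scaled = scaled,
                 signatures = signatures, combo_index = combo_index,
                 constraints = constraints, clusters = clusters,
                 enrich_go = enrich_go, enrich_tfsf = enrich_tfsf,
                 important = important, groups = groups, ttests = ttests,
                 manifest = manifest))
}

#' Generate a synthetic fixture directory
#'
#' Thin wrapper over [make_truth()] and [write_fixtures()]: creates
#' `expression.tsv`, `network.tsv`, `go.tsv` and `truth.json` under
#' `outdir`.
#'
#' @param outdir Output directory.
#' @param seed Master seed.
#' @param ... Passed to [make_truth()] (e.g. `n_genes`, `noise_sd`).
#' @return Named character vector of file paths, invisibly.
#' @export
simulate_fixtures <- function(outdir, seed = 1L, ...) {
  truth <- make_truth(seed = seed, ...)
  write_fixtures(truth, outdir, seed = seed)
}
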