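#' Right-tail Fisher (hypergeometric) over-representation p-value
#'
#' Probability of observing at least `n_hit` unit genes in the cluster
#' sample under the hypergeometric null: `P(X >= n_hit)` with
#' `X ~ Hypergeom(n_genome, n_unit_genome, n_cluster)`. Computed by exact
#' tail summation (no normal approximation). This is the one-sided Fisher
#' exact test of enrichment of a gene category within a cluster.
#'
#' @param n_hit Cluster DEGs belonging to the unit.
#' @param n_cluster DEGs in the cluster (sample size).
#' @param n_unit_genome Universe genes belonging to the unit.
#' @param n_genome Universe size.
#' @return p-value in (0, 1]. Vectorised over its arguments.
#' @export
#' @examples
#' fisher_right_tail(4, 4, 5, 10)  # 1/42
fisher_right_tail <- function(n_hit, n_cluster, n_unit_genome, n_genome) {
  n <- max(length(n_hit), length(n_cluster), length(n_unit_genome),
           length(n_genome))
  n_hit <- rep_len(as.numeric(n_hit), n)
  n_cluster <- rep_len(as.numeric(n_cluster), n)
  n_unit_genome <- rep_len(as.numeric(n_unit_genome), n)
  n_genome <- rep_len(as.numeric(n_genome), n)
  if (any(n_hit < 0)) stop("n_hit must be >= 0")
  if (any(n_hit > pmin(n_cluster, n_unit_genome))) {
    stop("n_hit exceeds min(n_cluster, n_unit_genome)")
  }
  if (any(pmax(n_cluster, n_unit_genome) > n_genome)) {
    stop("n_cluster and n_unit_genome must not exceed n_genome")
  }
  stats::phyper(n_hit - 1, n_unit_genome, n_genome - n_unit_genome,
                n_cluster, lower.tail = FALSE)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Family-wise error-rate correction: the i-th smallest p-value is
#' multiplied by (m - i + 1), a running maximum enforces monotonicity, and
#' values are capped at 1; results are returned in the input order.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' holm_bonferroni(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
holm_bonferroni <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "holm")
}

# Normalise the units argument: a combination index or GO map is a named
# list of gene-id vectors; a two-column data.frame (gene, category) is
# accepted and inverted.
as_unit_map <- function(units) {
  if (is.data.frame(units)) {
    stopifnot(ncol(units) >= 2L)
    return(lapply(split(as.character(units[[1L]]), units[[2L]]), unique))
  }
  stopifnot(is.list(units), !is.null(names(units)))
  units
}

#' Cluster over-representation analysis
#'
#' Tests every (cluster, unit) pair for over-representation of the unit's
#' genes among the cluster's DEGs with the right-tail Fisher exact test,
#' using the three counts: DEGs in the cluster, cluster DEGs in the unit,
#' and universe genes in the unit, against the universe size. The same
#' routine serves both stages of the pipeline: GO biological-process
#' categories and TF/SF regulator combinations (activation and repression
#' of the same TF/SF pair are distinct units). Holm-Bonferroni correction
#' is applied across all emitted tests of the call (one stage = one
#' family). A record is selected ("important") when it covers at least
#' `config$min_genes` cluster DEGs at adjusted p below
#' `config$alpha_enrich`. Pairs with zero overlap are not emitted.
#'
#' @param clusters A `"cluster_result"` or named assignment vector over the
#'   DEGs.
#' @param units Named list mapping unit id (GO category or combination key)
#'   to its gene set, or a two-column data.frame (gene, unit).
#' @param universe Character vector: the background gene universe.
#' @param config A [pipeline_config()].
#' @return data.frame of class `"enrichment_result"` with columns `cluster`,
#'   `unit`, `n_cluster`, `n_hit`, `n_unit_genome`, `n_genome`, `p_raw`,
#'   `p_adj`, `selected`.
#' @export
enrich_clusters <- function(clusters, units, universe,
                            config = pipeline_config()) {
  assignments <- cluster_assignments(clusters)
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty gene universe")
  units <- as_unit_map(units)
  units <- lapply(units, function(g) intersect(g, universe))
  n_genome <- length(universe)
  in_universe <- names(assignments) %in% universe
  assignments <- assignments[in_universe]
  by_cluster <- split(names(assignments), assignments)
  rows <- list()
  for (cl in names(by_cluster)) {
    members <- by_cluster[[cl]]
    n_cluster <- length(members)
    hits <- vapply(units, function(g) length(intersect(g, members)), integer(1L))
    keep <- hits >= 1L
    if (!any(keep)) next
    rows[[cl]] <- data.frame(
      cluster = cl,
      unit = names(units)[keep],
      n_cluster = n_cluster,
      n_hit = unname(hits[keep]),
      n_unit_genome = unname(lengths(units)[keep]),
      n_genome = n_genome,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    out <- data.frame(cluster = character(0), unit = character(0),
                      n_cluster = integer(0), n_hit = integer(0),
                      n_unit_genome = integer(0), n_genome = integer(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      selected = logical(0))
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_raw <- fisher_right_tail(out$n_hit, out$n_cluster,
                                 out$n_unit_genome, out$n_genome)
  out$p_adj <- holm_bonferroni(out$p_raw)
  out$selected <- out$n_hit >= config$min_genes & out$p_adj < config$alpha_enrich
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Important units across clusters
#'
#' A TF/SF combination (or GO category) is important when it is selected in
#' at least one cluster; each unit appears once regardless of how many
#' clusters select it.
#'
#' @param records An `"enrichment_result"`.
#' @return Sorted character vector of unit ids.
#' @export
select_important <- function(records) {
  sort(unique(records$unit[records$selected]))
}

#' Export GO enrichment for REVIGO
#'
#' Writes the two-column term list (GO id, nominal Fisher p-value) accepted
#' by the REVIGO web service; one test per line, smallest p per term when a
#' term is enriched in several clusters. The service itself is never
#' called.
#'
#' @param records GO-stage `"enrichment_result"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_revigo <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("term_id\tp_value", con)
  if (nrow(records) > 0L) {
    p <- vapply(split(records$p_raw, records$unit), min, numeric(1L))
    writeLines(sprintf("%s\t%.6e", names(p), p), con)
  }
  invisible(path)
}
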