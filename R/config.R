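#' Pipeline configuration
#'
#' Bundles every tunable threshold of the analysis in one validated object.
#' The defaults are the study conditions of the published analysis: DEGs are
#' genes reaching |log2 fold change| >= 1.5 at one or more sampling points,
#' an enrichment unit is called important in a cluster when it covers at
#' least 9 cluster DEGs at a Holm-corrected p below 0.0025, and a
#' co-regulation group is decisive when both its Fisher and best t-test
#' corrected p fall below 0.05.
#'
#' @param deg_threshold Absolute log2 fold-change cutoff defining a
#'   differentially expressed gene (default 1.5). Inclusive: a gene whose
#'   largest excursion equals the threshold is a DEG.
#' @param min_genes Minimum number of cluster DEGs an enrichment unit must
#'   cover to be selected as important (default 9).
#' @param alpha_enrich Corrected-p cutoff for enrichment selection
#'   (default 0.0025).
#' @param alpha_level Corrected-p cutoff for the level-hierarchy Fisher and
#'   t-tests (default 0.05).
#' @param k_min,k_max Cluster-number search range for [select_k()]
#'   (default 2 to 30).
#' @param repeats_per_k Seeded k-means restarts per candidate k (default 20).
#' @param seed Master seed; every random stage derives its own seed from it.
#' @param max_pairs Upper bound on generated must-link constraints.
#' @param universe Background universe rule for enrichment: `"annotation"`
#'   (genes present in the annotation/network table and in the expression
#'   matrix) or `"array"` (all genes detected on the array, i.e. all matrix
#'   rows).
#'
#' @return A list of class `"regpulse_config"`.
#' @export
#' @examples
#' cfg <- pipeline_config(k_max = 10, repeats_per_k = 5, seed = 7)
#' cfg$deg_threshold
pipeline_config <- function(deg_threshold = 1.5,
                            min_genes = 9L,
                            alpha_enrich = 0.0025,
                            alpha_level = 0.05,
                            k_min = 2L,
                            k_max = 30L,
                            repeats_per_k = 20L,
                            seed = 1L,
                            max_pairs = 10000L,
                            universe = c("annotation", "array")) {
  stopifnot(
    is.numeric(deg_threshold), length(deg_threshold) == 1L, deg_threshold > 0,
    is.numeric(min_genes), length(min_genes) == 1L, min_genes >= 1,
    is.numeric(alpha_enrich), alpha_enrich > 0, alpha_enrich < 1,
    is.numeric(alpha_level), alpha_level > 0, alpha_level < 1,
    is.numeric(k_min), k_min >= 1,
    is.numeric(k_max), k_max >= k_min,
    is.numeric(repeats_per_k), repeats_per_k >= 1,
    is.numeric(seed), length(seed) == 1L,
    is.numeric(max_pairs), max_pairs >= 1
  )
  structure(
    list(
      deg_threshold = as.numeric(deg_threshold),
      min_genes = as.integer(min_genes),
      alpha_enrich = as.numeric(alpha_enrich),
      alpha_level = as.numeric(alpha_level),
      k_min = as.integer(k_min),
      k_max = as.integer(k_max),
      repeats_per_k = as.integer(repeats_per_k),
      seed = as.integer(seed),
      max_pairs = as.integer(max_pairs),
      universe = match.arg(universe)
    ),
    class = "regpulse_config"
  )
}

#' @export
print.regpulse_config <- function(x, ...) {
  cat("regpulse pipeline configuration\n")
  cat(sprintf("  DEG threshold (|log2FC|): %g\n", x$deg_threshold))
  cat(sprintf("  enrichment selection: >= %d genes, corrected p < %g\n",
              x$min_genes, x$alpha_enrich))
  cat(sprintf("  level-analysis alpha: %g\n", x$alpha_level))
  cat(sprintf("  k search: %d..%d, %d restarts per k, seed %d\n",
              x$k_min, x$k_max, x$repeats_per_k, x$seed))
  cat(sprintf("  enrichment universe: %s\n", x$universe))
  invisible(x)
}

# Deterministic per-stage seed derivation from the master seed.
# All stage seeds are drawn once from one seeded stream so that any stage can
# be reproduced in isolation; values stay below 2^31.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}
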