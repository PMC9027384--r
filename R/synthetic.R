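#' @title Synthetic ground-truth generator
#' @name synthetic_data
#' @description
#' Builds fully deterministic fixtures that mirror the structure of a pulse
#' perturbation transcriptome study: piecewise-linear archetype time
#' profiles (immediate down with recovery, delayed persistent down, delayed
#' transient up, ...), planted clusters of genes following each archetype
#' with additive Gaussian noise on the log2 fold changes, a TF/SF
#' interaction table in which planted "important" combinations control a
#' block of genes inside one target cluster, decoy combinations wired at
#' random, and GO category memberships concentrated in planted clusters.
#' Every stage of the analysis pipeline can therefore be verified against
#' known truth without downloading anything.
NULL

default_archetypes <- function() {
  list(
    immediate_down_recover = list(
      t = c(0, 0.5, 4, 8, 15, 25), v = c(0, -2.5, -2.5, -1.2, 0, 0)),
    immediate_down_persistent = list(
      t = c(0, 0.5, 25), v = c(0, -2.2, -2.3)),
    delayed_down_persistent = list(
      t = c(0, 3, 8, 25), v = c(0, 0, -2, -2.1)),
    immediate_up_transient = list(
      t = c(0, 0.5, 2, 5, 25), v = c(0, 2.2, 1.8, 0, 0)),
    delayed_up_transient = list(
      t = c(0, 5, 10, 15, 20, 25), v = c(0, 0, 2.2, 2.2, 0, 0)),
    delayed_up_persistent = list(
      t = c(0, 4, 10, 25), v = c(0, 0, 2.2, 2.3)),
    delayed_up_recover = list(
      t = c(0, 1, 2.5, 5, 9, 25), v = c(0, 0.5, 2.5, 2.2, 0, 0)),
    flat_background = list(
      t = c(0, 25), v = c(0, 0))
  )
}

#' Define a synthetic ground truth
#'
#' Fixes every structural property of a synthetic study: gene ids, sampling
#' times, archetype profiles, planted cluster memberships, the planted and
#' decoy TF/SF combinations, planted GO categories, and the noise level.
#' Genes are laid out in consecutive blocks per archetype; the final
#' archetype is a flat non-differential background. Each planted
#' combination controls enough genes inside its target cluster
#' (`n_controlled >= 15`) to make the important-combination selection rule
#' (>= 9 genes at corrected p < 0.0025) achievable.
#'
#' @param n_genes Total number of genes (default 1200).
#' @param times Sampling times in hours post-pulse; the default 10 points
#'   span 0.5 to 25 h.
#' @param cluster_sizes Sizes of the seven differential archetype clusters;
#'   the remainder of `n_genes` is flat background.
#' @param noise_sd Gaussian noise standard deviation on log2 fold changes
#'   (default 0.2).
#' @param leak Fraction of each planted combination's targets wired outside
#'   its target cluster (default 0.1).
#' @param n_decoys Number of decoy TF/SF combinations (default 30).
#' @param n_go_decoys Number of decoy GO categories (default 20).
#' @param seed Seed stored with the truth; the downstream simulators
#'   consume it.
#' @return List of class `"synthetic_truth"`; notable fields:
#'   `gene_ids`, `times`, `archetypes`, `cluster_of` (0 = background),
#'   `k_planted`, `planted_combos`, `planted_go`, `decoys`, `noise_sd`.
#' @export
make_truth <- function(n_genes = 1200L,
                       times = c(0.5, 1, 2.5, 4, 6, 9, 12, 15, 20, 25),
                       cluster_sizes = c(180L, 150L, 120L, 110L, 100L, 90L, 80L),
                       noise_sd = 0.2,
                       leak = 0.1,
                       n_decoys = 30L,
                       n_go_decoys = 20L,
                       seed = 1L) {
  archetypes <- default_archetypes()
  n_deg_arch <- length(archetypes) - 1L
  if (length(cluster_sizes) != n_deg_arch) {
    stop("cluster_sizes must have one entry per differential archetype (",
         n_deg_arch, ")")
  }
  if (sum(cluster_sizes) > n_genes) {
    stop("cluster sizes sum (", sum(cluster_sizes),
         ") exceeds n_genes (", n_genes, ")")
  }
  rng <- range(unlist(lapply(archetypes, `[[`, "v")))
  stopifnot(rng[1] >= -3, rng[2] <= 3)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  cluster_of <- rep(0L, n_genes)
  cluster_of[seq_len(sum(cluster_sizes))] <-
    rep(seq_len(n_deg_arch), cluster_sizes)
  names(cluster_of) <- gene_ids
  planted_combos <- data.frame(
    tf = c("CRP-cAMP", "FlhDC", "ArcA", "FNR", "GadE", "PurR"),
    sf = c("RpoD", "RpoF", "RpoD", "RpoD", "RpoS", "RpoD"),
    mode = c("activation", "activation", "repression", "activation",
             "activation", "repression"),
    cluster = 1:6,
    n_controlled = c(20L, 18L, 16L, 15L, 17L, 15L),
    stringsAsFactors = FALSE
  )
  if (any(planted_combos$n_controlled < 15L)) {
    stop("each planted combination must control >= 15 genes in its cluster")
  }
  if (any(planted_combos$n_controlled > cluster_sizes[planted_combos$cluster])) {
    stop("planted combination larger than its target cluster")
  }
  planted_go <- data.frame(
    go_id = c("GO:0006099", "GO:0040011", "GO:0006979", "GO:0006537"),
    cluster = c(1L, 2L, 5L, 6L),
    n_genes = c(22L, 20L, 18L, 16L),
    stringsAsFactors = FALSE
  )
  structure(
    list(n_genes = as.integer(n_genes),
         times = times,
         archetypes = archetypes,
         cluster_sizes = as.integer(cluster_sizes),
         background_size = as.integer(n_genes - sum(cluster_sizes)),
         gene_ids = gene_ids,
         cluster_of = cluster_of,
         k_planted = n_deg_arch,
         planted_combos = planted_combos,
         planted_go = planted_go,
         n_decoys = as.integer(n_decoys),
         n_go_decoys = as.integer(n_go_decoys),
         leak = leak,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("synthetic truth: %d genes (%d background), %d archetype",
                     " clusters, %d planted combos, noise sd %g\n"),
              x$n_genes, x$background_size, x$k_planted,
              nrow(x$planted_combos), x$noise_sd))
  invisible(x)
}

# Archetype profile evaluated at the truth's sampling times.
archetype_profile <- function(arch, times) {
  stats::approx(arch$t, arch$v, xout = times, rule = 2)$y
}

#' Planted combination keys of a truth object
#' @param truth A `"synthetic_truth"`.
#' @return Character vector of `"TF/SF:mode"` keys.
#' @export
planted_combo_keys <- function(truth) {
  with(truth$planted_combos, combo_key(tf, sf, mode))
}

#' Simulate the expression matrix of a synthetic truth
#'
#' Each gene's profile is its cluster archetype (linear interpolation of
#' the anchor values at the truth's sampling times) plus iid Gaussian noise
#' per cell; background genes are pure noise. Deterministic given `seed`.
#'
#' @param truth A `"synthetic_truth"`.
#' @param noise_sd Noise standard deviation; defaults to the truth's value.
#' @param seed Integer seed; defaults to the truth's.
#' @return A time-course matrix (genes x times) of log2 fold changes.
#' @export
simulate_expression <- function(truth, noise_sd = truth$noise_sd,
                                seed = truth$seed) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  profs <- vapply(truth$archetypes, archetype_profile, numeric(length(truth$times)),
                  times = truth$times)
  arch_idx <- ifelse(truth$cluster_of == 0L, ncol(profs), truth$cluster_of)
  base <- t(profs[, arch_idx, drop = FALSE])
  set.seed(as.integer(seed))
  noise <- matrix(stats::rnorm(length(base), 0, noise_sd), nrow(base))
  time_course_matrix(base + noise, truth$gene_ids, truth$times)
}

#' Simulate the TF/SF interaction table and GO annotation
#'
#' Wires each planted combination to `n_controlled` genes sampled inside
#' its target cluster plus a `leak` fraction sampled outside it; decoy
#' combinations and decoy GO categories are wired uniformly at random over
#' all genes. Planted GO categories are wired like planted combinations.
#' Deterministic given `seed`.
#'
#' @param truth A `"synthetic_truth"`.
#' @param seed Integer seed; defaults to the truth's.
#' @param leak Leak fraction; defaults to the truth's.
#' @return List with `interactions` (data.frame tf/sf/gene/mode) and `go`
#'   (data.frame gene/category).
#' @export
simulate_network <- function(truth, seed = truth$seed, leak = truth$leak) {
  set.seed(as.integer(seed))
  genes <- truth$gene_ids
  wire <- function(cluster, n) {
    inside <- genes[truth$cluster_of == cluster]
    outside <- genes[truth$cluster_of != cluster]
    n_leak <- round(leak * n)
    c(sample(inside, n), if (n_leak > 0L) sample(outside, n_leak))
  }
  pc <- truth$planted_combos
  inter <- do.call(rbind, lapply(seq_len(nrow(pc)), function(i) {
    tg <- wire(pc$cluster[i], pc$n_controlled[i])
    data.frame(tf = pc$tf[i], sf = pc$sf[i], gene = tg, mode = pc$mode[i],
               stringsAsFactors = FALSE)
  }))
  if (truth$n_decoys > 0L) {
    # Decoy regulons mimic the many real regulators that do not respond to
    # the perturbation: small (below the min_genes selection threshold),
    # with co-expressed targets concentrated in one uniformly chosen home
    # cluster (0 = background) plus the same leak fraction as planted ones.
    decoys <- do.call(rbind, lapply(seq_len(truth$n_decoys), function(i) {
      sz <- sample(4:7, 1L)  # with leak, always < min_genes targets per cluster
      home <- sample(0:truth$k_planted, 1L)
      data.frame(tf = sprintf("Ydk%02d", i),
                 sf = sample(c("RpoD", "RpoS", "RpoN", "RpoF"), 1L),
                 gene = wire(home, sz),
                 mode = sample(c("activation", "repression"), 1L),
                 stringsAsFactors = FALSE)
    }))
    inter <- rbind(inter, decoys)
  }
  pg <- truth$planted_go
  go <- do.call(rbind, lapply(seq_len(nrow(pg)), function(i) {
    data.frame(gene = wire(pg$cluster[i], pg$n_genes[i]),
               category = pg$go_id[i], stringsAsFactors = FALSE)
  }))
  if (truth$n_go_decoys > 0L) {
    go_decoys <- do.call(rbind, lapply(seq_len(truth$n_go_decoys), function(i) {
      sz <- sample(15:40, 1L)
      data.frame(gene = sample(genes, sz),
                 category = sprintf("GO:00990%02d", i),
                 stringsAsFactors = FALSE)
    }))
    go <- rbind(go, go_decoys)
  }
  list(interactions = unique(inter), go = unique(go))
}

#' Write synthetic fixture files
#'
#' Emits the exact input dialects the pipeline consumes: `expression.tsv`
#' (gene x time log2 fold changes), `network.tsv` (tf, sf, gene, effect),
#' `go.tsv` (gene, category) and `truth.json` (the generating truth).
#' Byte-identical across runs with the same truth and seed.
#'
#' @param truth A `"synthetic_truth"`.
#' @param dir Output directory (created if needed).
#' @param seed Master seed; expression and network draws use seeds derived
#'   from it. Defaults to the truth's seed.
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixtures <- function(truth, dir, seed = truth$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 2L)
  x <- simulate_expression(truth, seed = seeds[1L])
  net <- simulate_network(truth, seed = seeds[2L])
  paths <- c(expression = file.path(dir, "expression.tsv"),
             network = file.path(dir, "network.tsv"),
             go = file.path(dir, "go.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression(x, paths[["expression"]])
  utils::write.table(net$interactions, paths[["network"]], sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     col.names = c("regulator", "sigma_factor", "target_gene",
                                   "effect"))
  utils::write.table(net$go, paths[["go"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("gene", "category"))
  truth_json <- truth
  truth_json$archetypes <- lapply(truth_json$archetypes, function(a) {
    list(t = a$t, v = a$v)
  })
  jsonlite::write_json(unclass(truth_json), paths[["truth"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
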