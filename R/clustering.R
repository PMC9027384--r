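#' @title Must-link constrained k-means with silhouette model selection
#' @name clustering
#' @description
#' Lloyd's algorithm extended with must-link background knowledge: genes
#' connected by must-links are merged (transitive closure) into blocks that
#' are assigned to centroids atomically, represented by their size-weighted
#' member centroid. With must-links only the constraints are always
#' satisfiable. The number of clusters is chosen by maximising the mean
#' silhouette index over repeated seeded restarts.
NULL

# Transitive closure of must-links over the rows of x -> integer block id
# per gene (union-find with path compression).
mustlink_blocks <- function(gene_ids, must_links) {
  parent <- seq_along(gene_ids)
  idx <- seq_along(gene_ids)
  names(idx) <- gene_ids
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (NROW(must_links) > 0L) {
    a <- idx[must_links[, 1L]]
    b <- idx[must_links[, 2L]]
    if (anyNA(a) || anyNA(b)) {
      bad <- must_links[which(is.na(a) | is.na(b))[1L], ]
      stop("must-link references gene absent from data: ",
           paste(bad, collapse = " - "))
    }
    for (j in seq_along(a)) {
      ra <- find(a[j]); rb <- find(b[j])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_along(parent), find, integer(1L))
  match(roots, unique(roots))
}

# squared euclidean distances rows(u) x rows(cent)
.sqdist <- function(u, cent) {
  d2 <- matrix(rowSums(u^2), nrow(u), nrow(cent)) -
    2 * tcrossprod(u, cent) +
    matrix(rowSums(cent^2), nrow(u), nrow(cent), byrow = TRUE)
  pmax(d2, 0)
}

#' Constrained k-means clustering
#'
#' Partitions scaled gene profiles into `k` clusters under must-link
#' constraints. Must-link groups are collapsed to single weighted units (the
#' centroid of their members) before Lloyd iteration, so every returned
#' assignment satisfies all must-links by construction. Empty clusters are
#' re-seeded from the unit farthest from its centroid (first index on ties),
#' keeping exactly `k` non-empty clusters. Deterministic given `seed`.
#'
#' @param x Numeric matrix, genes x time points (typically the output of
#'   [scale_profiles()]).
#' @param k Number of clusters, `1 <= k <=` number of must-link blocks.
#' @param constraints A `"constraint_set"` or `NULL`. Cannot-links are not
#'   supported by this solver and raise an error.
#' @param seed Integer seed for centroid initialisation.
#' @param max_iter Iteration cap for Lloyd updates.
#' @param init `"random"` (k distinct units) or `"kmeans++"` (distance
#'   weighted seeding).
#' @return Named integer vector of cluster labels in `1..k`, one per gene.
#' @export
cop_kmeans <- function(x, k, constraints = NULL, seed = 1L,
                       max_iter = 100L, init = c("kmeans++", "random")) {
  init <- match.arg(init)
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n >= 1L, k >= 1L)
  if (k > n) stop("k (", k, ") exceeds number of genes (", n, ")")
  ml <- if (is.null(constraints)) matrix(character(0), ncol = 2L) else {
    if (nrow(constraints$cannot_links) > 0L) {
      stop("cannot-link constraints are not supported")
    }
    constraints$must_links
  }
  block <- mustlink_blocks(rownames(x), ml)
  nu <- max(block)
  if (k > nu) {
    stop("k (", k, ") exceeds the ", nu,
         " must-link blocks; constraints make this k infeasible")
  }
  w <- as.numeric(tabulate(block, nu))
  u <- rowsum(x, block) / w

  if (k == 1L) {
    out <- rep(1L, n)
    names(out) <- rownames(x)
    return(out)
  }

  set.seed(as.integer(seed))
  if (init == "random") {
    cent <- u[sample.int(nu, k), , drop = FALSE]
  } else {
    # greedy k-means++: each new centre is the best (lowest weighted
    # potential) of several D^2-sampled candidates
    n_cand <- 2L + as.integer(ceiling(log(k)))
    ctr <- sample.int(nu, 1L, prob = w)
    closest <- .sqdist(u, u[ctr, , drop = FALSE])[, 1L]
    for (j in seq_len(k - 1L)) {
      wt <- w * closest
      cand <- if (sum(wt) == 0) {
        setdiff(seq_len(nu), ctr)[1L]
      } else {
        sample.int(nu, min(n_cand, nu), prob = wt)
      }
      pot <- vapply(cand, function(ci) {
        sum(w * pmin(closest, .sqdist(u, u[ci, , drop = FALSE])[, 1L]))
      }, numeric(1L))
      pick <- cand[which.min(pot)]
      ctr <- c(ctr, pick)
      closest <- pmin(closest, .sqdist(u, u[pick, , drop = FALSE])[, 1L])
    }
    cent <- u[ctr, , drop = FALSE]
  }

  assign_prev <- integer(nu)
  for (iter in seq_len(max_iter)) {
    d2 <- .sqdist(u, cent)
    a <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters deterministically from the farthest unit
    repeat {
      cnt <- tabulate(a, k)
      empty <- which(cnt == 0L)
      if (length(empty) == 0L) break
      cur <- d2[cbind(seq_len(nu), a)]
      cur[cnt[a] == 1L] <- -Inf  # do not strip another cluster bare
      far <- which.max(cur)
      cent[empty[1L], ] <- u[far, ]
      d2[, empty[1L]] <- .sqdist(u, cent[empty[1L], , drop = FALSE])
      a[far] <- empty[1L]
      a_new <- max.col(-d2, ties.method = "first")
      a_new[far] <- empty[1L]
      a <- a_new
    }
    if (identical(a, assign_prev)) break
    assign_prev <- a
    grp <- factor(a, levels = seq_len(k))
    cent <- rowsum(u * w, grp) / as.numeric(rowsum(w, grp))
  }
  out <- a[block]
  names(out) <- rownames(x)
  out
}

#' Mean silhouette width of a partition
#'
#' Standard silhouette with Euclidean distance:
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where `a(i)` is the mean
#' distance of point i to its own cluster and `b(i)` the smallest mean
#' distance to another cluster. Points in singleton clusters score 0; a
#' point with `a(i) = 0` and a positive `b(i)` scores 1.
#'
#' @param d Full symmetric distance matrix (`as.matrix(dist(x))`), or a
#'   data matrix when `is_dist = FALSE`.
#' @param labels Cluster labels, one per point; at least two non-empty
#'   clusters are required.
#' @param is_dist Set `FALSE` to pass the raw data matrix instead.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_mean <- function(d, labels, is_dist = TRUE) {
  if (!is_dist) d <- as.matrix(stats::dist(d))
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop("silhouette undefined for a single cluster")
  n <- ncol(d)
  stopifnot(length(labels) == n)
  nk <- tabulate(labels, k)
  tot <- rowsum(d, labels)              # k x n: total distance point j -> cluster g
  pick <- cbind(labels, seq_len(n))
  a <- tot[pick] / pmax(nk[labels] - 1L, 1L)
  m <- tot / nk
  m[pick] <- Inf
  b <- do.call(pmin, lapply(seq_len(k), function(g) m[g, ]))
  s <- (b - a) / pmax(a, b)
  s[!is.finite(s)] <- 0
  s[nk[labels] == 1L] <- 0
  mean(s)
}

# Canonical cluster labels for reporting: clusters ordered by their mean
# profile over the first third of the time course, ascending, so strongly
# down-regulated clusters come first. Cosmetic only.
canonical_labels <- function(x, assignments) {
  k <- max(assignments)
  p <- ncol(x)
  early <- seq_len(max(1L, ceiling(p / 3)))
  score <- vapply(seq_len(k), function(g) {
    mean(x[assignments == g, early, drop = FALSE])
  }, numeric(1L))
  remap <- match(seq_len(k), order(score))
  out <- remap[assignments]
  names(out) <- names(assignments)
  out
}

#' Select the cluster number by the silhouette index
#'
#' For every candidate k in `config$k_min..config$k_max`, runs
#' `config$repeats_per_k` seeded restarts of [cop_kmeans()] and records the
#' mean and standard deviation of the silhouette index; the k with the
#' highest mean wins (ties go to the smallest k, favouring parsimony) and
#' the best-silhouette run at that k provides the final assignment. All
#' restart seeds derive from `config$seed`, so the whole selection is
#' reproducible. Final labels are renumbered so that down-regulated clusters
#' (lowest early-time mean profile) come first.
#'
#' @param x Scaled profile matrix (genes x times).
#' @param constraints Optional `"constraint_set"` of must-links.
#' @param config A [pipeline_config()].
#' @return List of class `"cluster_result"`: `k`, `assignments` (named
#'   integer vector), `silhouette_by_k` (data.frame k/mean/sd),
#'   `silhouette`, `seeds`, `best_seed`.
#' @export
select_k <- function(x, constraints = NULL, config = pipeline_config()) {
  x <- as.matrix(x)
  n <- nrow(x)
  ml <- if (is.null(constraints)) matrix(character(0), ncol = 2L) else constraints$must_links
  nu <- max(mustlink_blocks(rownames(x), ml))
  k_max <- min(config$k_max, nu, n - 1L)
  if (config$k_min > k_max) {
    stop("k range [", config$k_min, ", ", k_max, "] is empty for ", nu,
         " constraint blocks")
  }
  ks <- seq.int(config$k_min, k_max)
  seeds <- matrix(derive_seeds(config$seed, length(ks) * config$repeats_per_k),
                  nrow = length(ks))
  d <- as.matrix(stats::dist(x))
  sil <- matrix(NA_real_, length(ks), config$repeats_per_k)
  runs <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    best <- -Inf
    for (r in seq_len(config$repeats_per_k)) {
      a <- cop_kmeans(x, ks[i], constraints, seed = seeds[i, r])
      s <- silhouette_mean(d, a)
      sil[i, r] <- s
      if (s > best) {
        best <- s
        runs[[i]] <- list(assignments = a, seed = seeds[i, r])
      }
    }
  }
  means <- rowMeans(sil)
  sds <- apply(sil, 1L, stats::sd)
  i_best <- which(means == max(means))[1L]   # ties -> smallest k
  assignments <- canonical_labels(x, runs[[i_best]]$assignments)
  structure(
    list(k = ks[i_best],
         assignments = assignments,
         silhouette = means[i_best],
         silhouette_by_k = data.frame(k = ks, mean = means, sd = sds),
         seeds = seeds,
         best_seed = runs[[i_best]]$seed),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("constrained k-means result: k = %d (mean silhouette %.3f), %d genes\n",
              x$k, x$silhouette, length(x$assignments)))
  invisible(x)
}

# Accept a cluster_result or a bare named assignment vector.
cluster_assignments <- function(clusters) {
  if (inherits(clusters, "cluster_result")) clusters$assignments else {
    stopifnot(!is.null(names(clusters)))
    clusters
  }
}

#' Write cluster assignments and the silhouette trace
#'
#' @param result A `"cluster_result"`.
#' @param assignments_path,silhouette_path Output TSV paths (either may be
#'   `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_clusters <- function(result, assignments_path = NULL,
                           silhouette_path = NULL) {
  if (!is.null(assignments_path)) {
    utils::write.table(
      data.frame(gene = names(result$assignments),
                 cluster = unname(result$assignments)),
      assignments_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(silhouette_path)) {
    utils::write.table(result$silhouette_by_k, silhouette_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(assignments_path, silhouette_path))
}
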