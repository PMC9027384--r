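#' @title Co-regulation level hierarchy
#' @name coregulation
#' @description
#' Once the important TF/SF combinations are known, every DEG controlled by
#' at least one of them is assigned to the group defined by the exact
#' subset of important combinations controlling it. The cardinality of that
#' subset is the group's regulatory level: Level 1 groups are controlled by
#' a single important combination and none of the others, Level 2 groups by
#' exactly two, and so on. Each group is scored twice: a Fisher exact test
#' asks whether the group is enriched for DEGs changed in the group's own
#' direction, and per-timepoint one-sided two-sample t-tests ask whether
#' the group's expression shift differs from all remaining genes. Both
#' families are Holm-corrected within each level, and a group is decisive
#' only when both corrected p-values fall below the significance level.
NULL

#' Direction of change of each gene
#'
#' The direction of a profile is the sign of its largest excursion: the
#' value with the greatest absolute log2 fold change (first such time point
#' on ties). Zero profiles count as up.
#'
#' @param x Time-course matrix.
#' @return Named character vector, `"up"` or `"down"` per gene.
#' @export
gene_directions <- function(x) {
  idx <- apply(abs(x), 1L, which.max)
  v <- x[cbind(seq_len(nrow(x)), idx)]
  out <- ifelse(v < 0, "down", "up")
  names(out) <- rownames(x)
  out
}

#' Partition DEGs into co-regulation level groups
#'
#' Maps each DEG gene g to `S(g)` = signature(g) intersected with the
#' important combinations; genes with empty `S(g)` are excluded, and the
#' remaining genes are grouped by the exact subset `S`, with level =
#' `|S|`. Groups with fewer than 2 genes are retained but flagged
#' untestable (the t-test needs two observations per side). The group's
#' direction is the sign of the mean log2 fold change of its member genes
#' over all time points.
#'
#' @param deg A `deg_set` or character vector of DEG ids.
#' @param important Character vector of important combination keys (from
#'   [select_important()]); must be non-empty.
#' @param signatures Named list from [build_signatures()].
#' @param x Time-course matrix (unscaled log2 fold changes) providing the
#'   direction of each group.
#' @return List of class `"level_groups"`; each element has `id`, `combos`,
#'   `level`, `genes`, `direction`, `testable`, plus `fisher_p_raw`,
#'   `fisher_p_adj` and `decisive` fields filled by the downstream steps.
#' @export
assign_levels <- function(deg, important, signatures, x) {
  if (length(important) == 0L) stop("no important combinations supplied")
  ids <- intersect(deg_genes(deg), names(signatures))
  s <- lapply(signatures[ids], function(sig) sort(intersect(sig, important)))
  keep <- lengths(s) > 0L
  s <- s[keep]
  if (length(s) == 0L) {
    return(structure(list(), class = "level_groups"))
  }
  key <- vapply(s, paste, character(1L), collapse = " + ")
  members <- split(names(s), key)
  groups <- lapply(names(members), function(k) {
    genes <- sort(members[[k]])
    combos <- strsplit(k, " + ", fixed = TRUE)[[1L]]
    list(id = k,
         combos = combos,
         level = length(combos),
         genes = genes,
         direction = if (mean(x[genes, , drop = FALSE]) < 0) "down" else "up",
         testable = length(genes) >= 2L,
         fisher_p_raw = NA_real_,
         fisher_p_adj = NA_real_,
         decisive = FALSE)
  })
  ord <- order(vapply(groups, `[[`, integer(1L), "level"),
               vapply(groups, `[[`, character(1L), "id"))
  structure(groups[ord], class = "level_groups")
}

#' @export
print.level_groups <- function(x, ...) {
  cat(sprintf("%d co-regulation group(s) over levels %s\n", length(x),
              if (length(x)) paste(range(vapply(x, `[[`, integer(1L), "level")),
                                   collapse = "-") else "-"))
  invisible(x)
}

#' Summarise level groups as a data.frame
#' @param x A `"level_groups"` object.
#' @param ... Unused.
#' @return data.frame with one row per group.
#' @export
as.data.frame.level_groups <- function(x, ...) {
  data.frame(
    group = vapply(x, `[[`, character(1L), "id"),
    level = vapply(x, `[[`, integer(1L), "level"),
    n_genes = vapply(x, function(g) length(g$genes), integer(1L)),
    direction = vapply(x, `[[`, character(1L), "direction"),
    fisher_p_raw = vapply(x, `[[`, numeric(1L), "fisher_p_raw"),
    fisher_p_adj = vapply(x, `[[`, numeric(1L), "fisher_p_adj"),
    decisive = vapply(x, `[[`, logical(1L), "decisive"),
    genes = vapply(x, function(g) paste(g$genes, collapse = ","), character(1L)),
    stringsAsFactors = FALSE
  )
}

#' Direction-enrichment Fisher test of level groups
#'
#' For each group, tests whether membership in the group is associated with
#' being a DEG changed in the group's direction, via the right-tail Fisher
#' exact test on the 2x2 table (in group vs not) x (DEG in group direction
#' vs not) over the full gene universe. Raw p-values are Holm-corrected
#' within each regulatory level.
#'
#' @param groups A `"level_groups"` object.
#' @param x Time-course matrix over the universe (all measured genes).
#' @param deg A `deg_set` or character vector of DEG ids.
#' @param universe Background genes; default all rows of `x`.
#' @return The groups with `fisher_p_raw`/`fisher_p_adj` filled in.
#' @export
group_fisher <- function(groups, x, deg, universe = rownames(x)) {
  if (length(groups) == 0L) return(groups)
  universe <- unique(as.character(universe))
  n_genome <- length(universe)
  dirs <- gene_directions(x[intersect(universe, rownames(x)), , drop = FALSE])
  degs <- intersect(deg_genes(deg), universe)
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    genes <- intersect(g$genes, universe)
    n_grp <- length(genes)
    dir_degs <- degs[dirs[degs] == g$direction]
    n_unit <- length(dir_degs)
    n_hit <- length(intersect(genes, dir_degs))
    if (n_grp == 0L || n_unit == 0L || n_grp == n_genome) {
      warning("degenerate margins for group '", g$id, "'; p set to 1")
      groups[[i]]$fisher_p_raw <- 1
    } else {
      groups[[i]]$fisher_p_raw <- fisher_right_tail(n_hit, n_grp, n_unit, n_genome)
    }
  }
  lev <- vapply(groups, `[[`, integer(1L), "level")
  p <- vapply(groups, `[[`, numeric(1L), "fisher_p_raw")
  for (l in unique(lev)) {
    sel <- lev == l
    adj <- holm_bonferroni(p[sel])
    for (j in seq_along(which(sel))) {
      groups[[which(sel)[j]]]$fisher_p_adj <- adj[j]
    }
  }
  groups
}

#' Per-timepoint one-sided two-sample t-tests of level groups
#'
#' At every sampling time, compares the log2 fold changes of a group's
#' genes against those of all other measured genes with a pooled-variance
#' two-sample t-test, one-sided in the group's direction (lower tail for
#' down-regulated groups, upper tail for up-regulated ones). Raw p-values
#' are Holm-corrected across all (group x time point) tests within the same
#' regulatory level. Groups with fewer than 2 genes are skipped
#' (untestable); a time point where both samples are constant yields `NA`
#' with a warning.
#'
#' @param groups A `"level_groups"` object.
#' @param x Time-course matrix over all measured genes.
#' @param config A [pipeline_config()] (supplies `alpha_level` downstream).
#' @return data.frame of class `"timepoint_tests"`: `group`, `level`,
#'   `time`, `direction`, `t_stat`, `p_one_sided`, `p_adj`,
#'   `signed_log10_p` (negative for down-regulated groups).
#' @export
timepoint_ttests <- function(groups, x, config = pipeline_config()) {
  times <- tc_times(x)
  rows <- list()
  for (g in groups) {
    if (!g$testable) next
    genes <- intersect(g$genes, rownames(x))
    other <- setdiff(rownames(x), genes)
    if (length(genes) < 2L || length(other) < 2L) next
    alt <- if (g$direction == "down") "less" else "greater"
    for (j in seq_along(times)) {
      a <- x[genes, j]
      b <- x[other, j]
      res <- tryCatch(
        stats::t.test(a, b, alternative = alt, var.equal = TRUE),
        error = function(e) NULL
      )
      if (is.null(res)) {
        warning(sprintf("zero pooled variance for group '%s' at t = %g h",
                        g$id, times[j]))
        tj <- NA_real_; pj <- NA_real_
      } else {
        tj <- unname(res$statistic); pj <- res$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g$id, level = g$level, time = times[j],
        direction = g$direction, t_stat = tj, p_one_sided = pj,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(group = character(0), level = integer(0),
                      time = numeric(0), direction = character(0),
                      t_stat = numeric(0), p_one_sided = numeric(0),
                      p_adj = numeric(0), signed_log10_p = numeric(0))
    class(out) <- c("timepoint_tests", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (l in unique(out$level)) {
    sel <- out$level == l & !is.na(out$p_one_sided)
    out$p_adj[sel] <- holm_bonferroni(out$p_one_sided[sel])
  }
  out$signed_log10_p <- ifelse(out$direction == "down", -1, 1) *
    -log10(out$p_adj)
  class(out) <- c("timepoint_tests", "data.frame")
  out
}

#' Flag decisive co-regulation groups
#'
#' A group is decisive when its level-corrected Fisher p and its best
#' (smallest) level-corrected t-test p are both below `alpha_level`.
#'
#' @param groups A `"level_groups"` object after [group_fisher()].
#' @param ttests Output of [timepoint_ttests()].
#' @param alpha_level Dual-significance cutoff (default 0.05).
#' @return The groups with `decisive` set.
#' @export
decisive_flags <- function(groups, ttests, alpha_level = 0.05) {
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    pt_min <- suppressWarnings(
      min(ttests$p_adj[ttests$group == g$id], na.rm = TRUE))
    groups[[i]]$decisive <- isTRUE(!is.na(g$fisher_p_adj) &&
                                     g$fisher_p_adj < alpha_level &&
                                     is.finite(pt_min) &&
                                     pt_min < alpha_level)
  }
  groups
}

#' Run the whole level analysis
#'
#' Convenience wrapper chaining [assign_levels()], [group_fisher()],
#' [timepoint_ttests()] and [decisive_flags()].
#'
#' @inheritParams assign_levels
#' @inheritParams timepoint_ttests
#' @param universe Background for the Fisher stage; default all rows of `x`.
#' @return List with `groups` (decisive flags set) and `ttests`.
#' @export
coregulation_analysis <- function(deg, important, signatures, x,
                                  config = pipeline_config(),
                                  universe = rownames(x)) {
  groups <- assign_levels(deg, important, signatures, x)
  groups <- group_fisher(groups, x, deg, universe)
  tt <- timepoint_ttests(groups, x, config)
  groups <- decisive_flags(groups, tt, config$alpha_level)
  list(groups = groups, ttests = tt)
}

#' Export the per-timepoint significance heat-map
#'
#' Writes a TSV matrix with one row per tested group (labelled by its
#' combination set and level) and one column per time point; cells hold
#' signed `-log10` corrected p-values, negative for down-regulated groups.
#'
#' @param ttests Output of [timepoint_ttests()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(ttests, path) {
  con <- file(path, "w")
  on.exit(close(con))
  times <- sort(unique(ttests$time))
  writeLines(paste(c("group", "level", format(times, trim = TRUE)),
                   collapse = "\t"), con)
  if (nrow(ttests) > 0L) {
    for (gid in unique(ttests$group)) {
      sub <- ttests[ttests$group == gid, ]
      vals <- sub$signed_log10_p[match(times, sub$time)]
      writeLines(paste(c(gid, sub$level[1L],
                         formatC(vals, format = "g", digits = 12)),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}
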