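#' @title TF/SF regulatory-network tables and clustering constraints
#' @name regnet
#' @description
#' Parsers and transforms for RegulonDB-style regulator tables. A regulatory
#' "combination" is one unit of transcriptional control: a transcription
#' factor together with the sigma factor directing the polymerase and the
#' sign of the interaction, e.g. activation by CRP-cAMP under RpoD. Per-gene
#' sets of combinations ("signatures") drive both the enrichment tests and
#' the must-link constraints of the clustering stage.
NULL

# Canonical key for one (TF, SF, mode) combination.
combo_key <- function(tf, sf, mode) paste0(tf, "/", sf, ":", mode)

#' Split combination keys back into their parts
#' @param key Character vector of `"TF/SF:mode"` keys.
#' @return data.frame with columns `tf`, `sf`, `mode`.
#' @export
parse_combo <- function(key) {
  mode <- sub("^.*:", "", key)
  rest <- sub(":[^:]*$", "", key)
  data.frame(tf = sub("/[^/]*$", "", rest),
             sf = sub("^.*/", "", rest),
             mode = mode,
             stringsAsFactors = FALSE)
}

.mode_synonyms <- c(
  "+" = "activation", "activation" = "activation", "activator" = "activation",
  "act" = "activation", "a" = "activation", "1" = "activation",
  "-" = "repression", "repression" = "repression", "repressor" = "repression",
  "rep" = "repression", "inhibition" = "repression", "inh" = "repression",
  "r" = "repression", "-1" = "repression"
)

#' Read a TF/SF target-gene interaction table
#'
#' Parses a RegulonDB-export-style delimited table with four columns:
#' regulator (TF), sigma factor, target gene, effect. Effect tokens `+`,
#' `activation`, `act` (and case variants) mean activation; `-`,
#' `repression`, `inhibition` mean repression. Composite regulators such as
#' FlhDC are kept verbatim as single names. Exact duplicate rows are
#' collapsed.
#'
#' @param path Path to a tab- or comma-delimited file, with or without a
#'   header line (a header is detected when the fourth field is not a valid
#'   effect token).
#' @return data.frame with columns `tf`, `sf`, `gene`, `mode`
#'   (`"activation"`/`"repression"`), deduplicated.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty network file: ", path)
  sep <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad_ncol <- which(lengths(parts) < 4L)
  if (length(bad_ncol) > 0L) {
    stop("line ", bad_ncol[1L], ": expected 4 delimited fields")
  }
  tab <- do.call(rbind, lapply(parts, function(p) trimws(p[1:4])))
  first_line <- 1L
  if (is.na(.mode_synonyms[tolower(tab[1L, 4L])])) {
    # header row
    if (nrow(tab) == 1L) stop("network file holds only a header: ", path)
    tab <- tab[-1L, , drop = FALSE]
    first_line <- 2L
  }
  mode <- .mode_synonyms[tolower(tab[, 4L])]
  if (anyNA(mode)) {
    i <- which(is.na(mode))[1L]
    stop(sprintf("line %d: unknown effect token '%s'",
                 i + first_line - 1L, tab[i, 4L]))
  }
  out <- data.frame(tf = tab[, 1L], sf = tab[, 2L], gene = tab[, 3L],
                    mode = unname(mode), stringsAsFactors = FALSE)
  unique(out)
}

#' Build per-gene regulatory signatures
#'
#' Restricts an interaction table to a gene universe and collects, for each
#' universe gene, the set of (TF, SF, mode) combinations known to control
#' it. Genes without any known interaction get an empty signature.
#'
#' @param interactions data.frame from [read_network()].
#' @param universe Character vector of gene ids (typically the expression
#'   matrix rows).
#' @return Named list over `universe`; each element a sorted character
#'   vector of combination keys (`"TF/SF:mode"`), possibly empty.
#' @export
build_signatures <- function(interactions, universe) {
  universe <- as.character(universe)
  keep <- interactions$gene %in% universe
  n_out <- sum(!keep)
  if (n_out > 0L) {
    message(n_out, " interaction(s) target genes outside the universe; ignored")
  }
  interactions <- interactions[keep, , drop = FALSE]
  keys <- combo_key(interactions$tf, interactions$sf, interactions$mode)
  sig <- lapply(split(keys, factor(interactions$gene, levels = universe)),
                function(k) sort(unique(k)))
  sig[universe]
}

#' Invert signatures into a combination-indexed target map
#'
#' The combination index is the TF/SF target-gene network matrix in sparse
#' form: for each (TF, SF, mode) combination, the set of universe genes it
#' controls.
#'
#' @param signatures Named list from [build_signatures()].
#' @return Named list: combination key -> sorted character vector of genes.
#' @export
build_combination_index <- function(signatures) {
  genes <- rep(names(signatures), lengths(signatures))
  keys <- unlist(signatures, use.names = FALSE)
  if (length(keys) == 0L) return(structure(list(), names = character(0)))
  lapply(split(genes, keys), function(g) sort(unique(g)))
}

#' Create a constraint set
#'
#' @param must_links Two-column character matrix of unordered gene pairs
#'   that must share a cluster.
#' @param cannot_links Two-column character matrix of pairs that must not
#'   (default empty; the standard pipeline never generates any).
#' @return List of class `"constraint_set"`.
#' @export
constraint_set <- function(must_links = NULL, cannot_links = NULL) {
  norm <- function(m) {
    if (is.null(m) || NROW(m) == 0L) {
      return(matrix(character(0), ncol = 2L))
    }
    m <- matrix(as.character(m), ncol = 2L)
    t(apply(m, 1L, sort))
  }
  ml <- norm(must_links)
  cl <- norm(cannot_links)
  if (nrow(ml) > 0L && nrow(cl) > 0L) {
    both <- intersect(paste(ml[, 1L], ml[, 2L]), paste(cl[, 1L], cl[, 2L]))
    if (length(both) > 0L) stop("pair in both must- and cannot-links: ", both[1L])
  }
  structure(list(must_links = ml, cannot_links = cl), class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat(sprintf("constraint set: %d must-link, %d cannot-link pair(s)\n",
              nrow(x$must_links), nrow(x$cannot_links)))
  invisible(x)
}

#' Derive must-link constraints from regulatory signatures
#'
#' Encodes the TF/SF background knowledge for constrained clustering: DEGs
#' sharing an identical, non-empty regulatory signature are chained by
#' must-links (g1-g2, g2-g3, ... in gene-id order), which places each
#' identically-regulated group in one cluster while keeping the constraint
#' count linear in group size. Genes with empty signatures carry no evidence
#' of co-regulation and generate no constraints. When the total would exceed
#' `max_pairs`, chains from the largest groups are kept first (ties broken
#' by gene-id order) and the remainder dropped deterministically.
#'
#' @param signatures Named list from [build_signatures()].
#' @param deg A `deg_set` or character vector of DEG ids.
#' @param max_pairs Cap on the number of generated pairs.
#' @return A `"constraint_set"` with must-links only.
#' @export
derive_mustlinks <- function(signatures, deg, max_pairs = 10000L) {
  if (max_pairs < 1L) stop("max_pairs must be >= 1")
  ids <- deg_genes(deg)
  if (length(ids) == 0L) stop("empty DEG set")
  sig <- signatures[intersect(ids, names(signatures))]
  sig <- sig[lengths(sig) > 0L]
  if (length(sig) == 0L) return(constraint_set())
  key <- vapply(sig, paste, character(1L), collapse = "|")
  groups <- split(names(sig), key)
  groups <- lapply(groups, sort)
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) == 0L) return(constraint_set())
  ord <- order(-lengths(groups),
               vapply(groups, `[`, character(1L), 1L))
  groups <- groups[ord]
  pairs <- do.call(rbind, lapply(groups, function(g) {
    cbind(g[-length(g)], g[-1L])
  }))
  if (nrow(pairs) > max_pairs) pairs <- pairs[seq_len(max_pairs), , drop = FALSE]
  constraint_set(must_links = pairs)
}
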