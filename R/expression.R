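#' Construct and validate a time-course expression matrix
#'
#' The central data container of the package: a numeric matrix of log2 fold
#' changes relative to the pre-perturbation reference, one row per gene and
#' one column per sampling time (hours after the perturbation; time zero is
#' the perturbation itself, the reference sample is implicit in the ratios).
#'
#' @param values Numeric matrix (genes x times).
#' @param genes Character vector of unique gene identifiers (defaults to
#'   `rownames(values)`).
#' @param times Strictly increasing numeric sampling times in hours
#'   (defaults to `as.numeric(colnames(values))`).
#'
#' @return A validated numeric matrix with gene ids as row names and time
#'   labels as column names.
#' @export
#' @examples
#' m <- time_course_matrix(matrix(rnorm(6), 2, 3,
#'   dimnames = list(c("g1", "g2"), c(0.5, 1, 2))))
#' tc_times(m)
time_course_matrix <- function(values,
                               genes = rownames(values),
                               times = as.numeric(colnames(values))) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(genes)) stop("gene identifiers are required")
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    stop("duplicated gene id: ", genes[duplicated(genes)][1L])
  }
  if (length(genes) != nrow(values)) {
    stop("length of gene ids (", length(genes),
         ") does not match row count (", nrow(values), ")")
  }
  times <- as.numeric(times)
  if (anyNA(times)) stop("time labels must be numeric (hours post-pulse)")
  if (length(times) != ncol(values)) {
    stop("number of times does not match column count")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("sampling times must be strictly increasing")
  }
  if (anyNA(values)) stop("matrix contains missing values")
  dimnames(values) <- list(genes, format(times, trim = TRUE))
  values
}

#' Sampling times of a time-course matrix
#' @param x A matrix produced by [time_course_matrix()] or [read_expression()].
#' @return Numeric vector of hours post-perturbation.
#' @export
tc_times <- function(x) as.numeric(colnames(x))

#' Read a gene x time expression matrix
#'
#' Reads a tab- or comma-delimited file whose header row holds numeric time
#' labels (hours after the perturbation) and whose first column holds gene
#' identifiers; the remaining cells are log2 fold changes versus the
#' pre-perturbation reference.
#'
#' @param path Path to the delimited file. The delimiter (tab or comma) is
#'   detected from the header line.
#' @param missing_policy What to do with a gene having any missing or
#'   non-numeric value: `"drop_gene"` (default) removes it with a warning,
#'   `"error"` aborts naming the offending row and column.
#'
#' @return A validated time-course matrix (see [time_course_matrix()]); row
#'   order follows the file.
#' @seealso [write_expression()] for the inverse operation.
#' @export
read_expression <- function(path, missing_policy = c("drop_gene", "error")) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("expression file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs a gene column plus >= 1 time column")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) {
    stop("duplicated gene id: ", genes[duplicated(genes)][1L])
  }
  times <- suppressWarnings(as.numeric(colnames(df)[-1L]))
  if (anyNA(times)) {
    stop("header time labels must be numeric, got: ",
         paste(colnames(df)[-1L][is.na(times)], collapse = ", "))
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("sampling times must be strictly increasing")
  }
  vals <- suppressWarnings(
    vapply(df[-1L], function(col) as.numeric(col), numeric(nrow(df)))
  )
  vals <- matrix(vals, nrow = nrow(df))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    if (missing_policy == "error") {
      stop(sprintf("non-numeric or missing value for gene '%s' at time %s",
                   genes[bad[1L, 1L]], format(times[bad[1L, 2L]])))
    }
    drop <- unique(bad[, 1L])
    warning(sprintf("dropping %d gene(s) with missing values (e.g. '%s')",
                    length(drop), genes[drop[1L]]))
    vals <- vals[-drop, , drop = FALSE]
    genes <- genes[-drop]
  }
  time_course_matrix(vals, genes, times)
}

#' Write an expression matrix in the native TSV dialect
#'
#' Emits the same dialect [read_expression()] consumes: header
#' `gene<TAB>t1<TAB>t2...`, one row per gene, full double precision so a
#' read/write round trip is bit-exact.
#'
#' @param x Time-course matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  times <- tc_times(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", format(times, trim = TRUE)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], formatC(x[i, ], format = "g", digits = 17)),
          collapse = "\t")
  }, character(1L))
  writeLines(body, con)
  invisible(path)
}

#' Filter differentially expressed genes
#'
#' A gene is differentially expressed when its absolute log2 fold change
#' reaches the threshold at one or more sampling points. The comparison is
#' inclusive (`>=`), so a gene whose largest excursion equals the threshold
#' exactly is kept.
#'
#' @param x Time-course matrix.
#' @param threshold Positive absolute log2 fold-change cutoff (default 1.5).
#' @return An object of class `"deg_set"`: list with `gene_ids` (in matrix
#'   row order) and `threshold`.
#' @export
#' @examples
#' m <- time_course_matrix(rbind(a = c(0, 2), b = c(0.2, -0.4)),
#'                         times = c(1, 2))
#' filter_degs(m, 1.5)$gene_ids
filter_degs <- function(x, threshold = 1.5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  if (nrow(x) == 0L) stop("empty expression matrix")
  keep <- apply(abs(x), 1L, max) >= threshold
  structure(list(gene_ids = rownames(x)[keep], threshold = threshold),
            class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat(sprintf("DEG set: %d genes at |log2FC| >= %g\n",
              length(x$gene_ids), x$threshold))
  invisible(x)
}

# Accept either a deg_set or a bare character vector of gene ids.
deg_genes <- function(deg) {
  if (inherits(deg, "deg_set")) deg$gene_ids else as.character(deg)
}

#' Scale profiles to unit maximum absolute value
#'
#' Divides each selected gene's profile by its own maximum absolute log2
#' fold change, so every scaled profile peaks at +1 or -1 while keeping its
#' shape and signs. This puts strongly and weakly responding genes on a
#' common footing before clustering, and it is idempotent.
#'
#' @param x Time-course matrix.
#' @param genes A `deg_set` or character vector selecting the rows to scale
#'   and return; default all rows.
#' @return A time-course matrix of the selected genes with each row scaled
#'   to max |value| = 1.
#' @export
scale_profiles <- function(x, genes = rownames(x)) {
  ids <- deg_genes(genes)
  missing <- setdiff(ids, rownames(x))
  if (length(missing) > 0L) {
    stop("genes absent from matrix: ", paste(utils::head(missing, 3L), collapse = ", "))
  }
  sub <- x[ids, , drop = FALSE]
  m <- apply(abs(sub), 1L, max)
  if (any(m == 0)) {
    stop("cannot scale all-zero profile of gene: ", ids[which(m == 0)[1L]])
  }
  time_course_matrix(sub / m, ids, tc_times(x))
}
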