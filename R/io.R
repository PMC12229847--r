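#' Read a gene-by-sample expression or methylation matrix
#'
#' Reads a TSV whose header row holds sample identifiers and whose first
#' column holds gene identifiers. Duplicate gene rows are collapsed by their
#' mean (with a warning); methylation matrices are checked to lie in
#' \eqn{[0, 1]}. Missing entries are encoded as \code{NA}.
#'
#' @param path Path to a tab-separated file.
#' @param value_kind Either \code{"expression"} (log-scale expression) or
#'   \code{"methylation"} (per-gene methylation scores in \eqn{[0,1]}).
#' @return A numeric matrix (genes in rows, samples in columns) with a
#'   \code{"value_kind"} attribute.
#' @export
read_expression <- function(path, value_kind = c("expression", "methylation")) {
  value_kind <- match.arg(value_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = "NA")
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty or malformed matrix file: ", path)
  gene_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in ", path)
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s' in %s",
                 vals[bad[1L, 1L], bad[1L, 2L]], gene_ids[bad[1L, 1L]],
                 sample_ids[bad[1L, 2L]], path))
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    warning(length(dup), " duplicate gene id(s) collapsed by mean: ",
            paste(utils::head(dup, 5L), collapse = ", "))
    num <- rowsum(num, group = gene_ids, reorder = FALSE) /
      as.vector(table(factor(gene_ids, levels = unique(gene_ids))))
  }
  if (value_kind == "methylation") {
    rng <- range(num, na.rm = TRUE)
    if (rng[1L] < 0 || rng[2L] > 1)
      stop("methylation value out of [0,1]: found ",
           if (rng[2L] > 1) rng[2L] else rng[1L])
  }
  structure(num, value_kind = value_kind)
}

#' Read a clinical annotation table
#'
#' Expects a TSV with a \code{sample_id} column plus any of \code{stage}
#' (\code{early}/\code{advanced}), \code{grade} (\code{low}/\code{high}),
#' \code{time} (non-negative), \code{event} (\code{0}/\code{1}) and optional
#' binary outcome columns. \code{NA} marks missing values.
#'
#' @param path Path to a tab-separated file.
#' @return A data frame keyed by unique \code{sample_id}.
#' @export
read_clinical <- function(path) {
  cl <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, na.strings = "NA",
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(cl)) stop("clinical table lacks a sample_id column")
  if (anyDuplicated(cl$sample_id)) stop("duplicate sample_id in clinical table")
  if ("time" %in% colnames(cl) && any(cl$time < 0, na.rm = TRUE))
    stop("negative survival time in clinical table")
  if ("event" %in% colnames(cl) && !all(cl$event %in% c(0, 1, NA)))
    stop("event column must be 0/1/NA")
  cl
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, \code{name TAB description TAB
#' gene TAB gene ...}. Genes repeated within a line are deduplicated with a
#' warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors with a \code{"descriptions"}
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", f[1L], "' (line ", i, ") deduplicated")
      genes <- unique(genes)
    }
    sets[[f[1L]]] <- genes
    desc[f[1L]] <- f[2L]
  }
  structure(sets, descriptions = desc)
}

#' Read an undirected interaction edge list
#'
#' Reads a 3-column TSV in the STRING-export dialect (node, node, combined
#' score). Edges are canonicalized to an undirected form: self-loops are
#' dropped (with a warning), both orientations of a pair collapse to one
#' edge keeping the maximum score, and edges scoring below \code{min_score}
#' are removed (threshold inclusive: a score equal to \code{min_score} is
#' kept).
#'
#' @param path Path to a tab-separated file with columns
#'   \code{node_a}, \code{node_b}, \code{score} (header optional; the first
#'   two columns are nodes, the third the score).
#' @param min_score Minimum combined score to retain an edge, or \code{NULL}
#'   for no filtering.
#' @return A data frame with columns \code{node_a}, \code{node_b},
#'   \code{score}, one row per undirected edge, \code{node_a < node_b}.
#' @export
read_edges <- function(path, min_score = NULL) {
  first <- readLines(path, n = 1L)
  f1 <- strsplit(first, "\t", fixed = TRUE)[[1L]]
  has_header <- length(f1) >= 3L && is.na(suppressWarnings(as.numeric(f1[3L])))
  df <- utils::read.delim(path, header = has_header, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("edge list needs at least two node columns")
  if (ncol(df) == 2L) {
    if (!is.null(min_score)) stop("min_score set but edge list has no score column")
    df$score <- 1
  }
  edges <- data.frame(node_a = as.character(df[[1L]]),
                      node_b = as.character(df[[2L]]),
                      score = as.numeric(df[[3L]]),
                      stringsAsFactors = FALSE)
  canonicalize_edges(edges, min_score = min_score)
}

#' Canonicalize an edge list to undirected form
#'
#' @param edges Data frame with columns \code{node_a}, \code{node_b},
#'   \code{score}.
#' @param min_score Optional inclusive score threshold.
#' @return Canonical undirected edge data frame (see [read_edges()]).
#' @export
canonicalize_edges <- function(edges, min_score = NULL) {
  stopifnot(all(c("node_a", "node_b", "score") %in% colnames(edges)))
  loop <- edges$node_a == edges$node_b
  if (any(loop)) {
    warning(sum(loop), " self-loop(s) dropped")
    edges <- edges[!loop, , drop = FALSE]
  }
  a <- pmin(edges$node_a, edges$node_b)
  b <- pmax(edges$node_a, edges$node_b)
  key <- paste(a, b, sep = "\r")
  score <- as.vector(tapply(edges$score, key, max))
  keys <- names(tapply(edges$score, key, max))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(node_a = vapply(parts, `[`, "", 1L),
                    node_b = vapply(parts, `[`, "", 2L),
                    score = score, stringsAsFactors = FALSE)
  if (!is.null(min_score)) out <- out[out$score >= min_score, , drop = FALSE]
  out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a table with stable float rendering
#'
#' Writes a TSV with a header row. Numeric columns are rendered at 10
#' significant digits so repeated runs produce byte-identical files; missing
#' values become the literal \code{NA}.
#'
#' @param records A data frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      s <- formatC(v, digits = 10, format = "g")
      s[!is.finite(v) & !is.na(v)] <- as.character(v[!is.finite(v) & !is.na(v)])
      s[is.na(v)] <- NA_character_
      out[[j]] <- s
    }
  }
  ok <- tryCatch({
    utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) stop("cannot write table to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Write an expression/methylation matrix as TSV
#'
#' @param mat Numeric matrix with gene row names and sample column names.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, path)
}
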