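#' Rank genes by a two-group differential metric
#'
#' Computes a per-gene metric between two phenotype groups and returns genes
#' sorted by the metric, descending (ties broken by gene id). The metric is
#' oriented as group 2 minus group 1 (second factor level high), so genes up
#' in the second level rank first.
#'
#' \code{signal2noise} is the GSEA convention
#' \eqn{(\mu_2 - \mu_1)/(\sigma_1 + \sigma_2)} with each group SD floored at
#' \eqn{0.2 |\mu|} of its group mean (and a small absolute floor of 0.2 when
#' the mean is 0) to avoid division blow-ups; \code{tstat} is the
#' equal-variance two-sample t statistic.
#'
#' @param expr Genes-by-samples matrix.
#' @param labels Two-level factor aligned to columns.
#' @param metric \code{"signal2noise"} (each group needs \eqn{\ge 3}
#'   samples) or \code{"tstat"} (\eqn{\ge 2}).
#' @return Named numeric vector of metric values, sorted descending.
#' @export
rank_by_groups <- function(expr, labels, metric = c("signal2noise", "tstat")) {
  metric <- match.arg(metric)
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2L) stop("rank_by_groups needs exactly two groups")
  n1 <- sum(labels == levels(labels)[1L])
  n2 <- sum(labels == levels(labels)[2L])
  min_n <- if (metric == "signal2noise") 3L else 2L
  if (min(n1, n2) < min_n)
    stop("each group needs at least ", min_n, " samples for metric ", metric)
  x1 <- expr[, labels == levels(labels)[1L], drop = FALSE]
  x2 <- expr[, labels == levels(labels)[2L], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  if (metric == "signal2noise") {
    s1 <- sqrt(rowSums((x1 - m1)^2) / (n1 - 1L))
    s2 <- sqrt(rowSums((x2 - m2)^2) / (n2 - 1L))
    s1 <- pmax(s1, 0.2 * abs(m1), 0.2 * (m1 == 0))
    s2 <- pmax(s2, 0.2 * abs(m2), 0.2 * (m2 == 0))
    met <- (m2 - m1) / (s1 + s2)
  } else {
    v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
    v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    met <- ifelse(se > 0, (m2 - m1) / se, 0)
  }
  names(met) <- rownames(expr)
  met[order(-met, names(met))]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The standard GSEA running sum over a ranked gene list: at each set gene
#' (hit) the sum increases by \eqn{|m|^{weight}} normalized by the total over
#' set hits; at each non-set gene it decreases by \eqn{1/(N - |S|)}. The
#' enrichment score (ES) is the extremum of the running sum; the leading
#' edge is the set genes at or before the extremum (for positive ES; at or
#' after it for negative ES).
#'
#' @param ranked Named numeric vector sorted descending (see
#'   [rank_by_groups()]).
#' @param geneset Character vector; must share at least one gene with the
#'   ranked list and not cover it entirely.
#' @param weight Exponent on the metric (0 gives the unweighted KS walk;
#'   default 1, the GSEA convention).
#' @return List with \code{ES}, \code{running_sum} (length N) and
#'   \code{leading_edge}.
#' @export
enrichment_score <- function(ranked, geneset, weight = 1) {
  N <- length(ranked)
  hit <- names(ranked) %in% geneset
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("gene set has no overlap with the ranked list")
  if (n_hit == N) stop("gene set covers the whole ranked list")
  w <- abs(ranked)^weight
  inc <- numeric(N)
  denom_hit <- sum(w[hit])
  inc[hit] <- if (denom_hit > 0) w[hit] / denom_hit else 1 / n_hit
  inc[!hit] <- -1 / (N - n_hit)
  running <- cumsum(inc)
  i_ext <- which.max(abs(running))
  es <- running[i_ext]
  leading <- if (es >= 0) names(ranked)[seq_len(i_ext)][hit[seq_len(i_ext)]]
  else names(ranked)[i_ext:N][hit[i_ext:N]]
  list(ES = es, running_sum = running, leading_edge = leading)
}

#' Permutation test for gene-set enrichment
#'
#' Computes the observed ES of a set in the ranked list derived from a
#' two-group phenotype, then builds a permutation null: \code{phenotype}
#' permutes the sample labels and recomputes ranking and ES;
#' \code{geneset} redraws random sets of the same size from the measured
#' genes (for tiny cohorts). The normalized enrichment score (NES) is the
#' observed ES divided by the mean |null ES| of matching sign, and the
#' nominal p-value is two-sided on |ES|:
#' \eqn{(1 + \#\{|ES_{null}| \ge |ES|\}) / (n_{perm} + 1)}.
#'
#' @param expr Genes-by-samples matrix.
#' @param labels Two-level factor aligned to columns.
#' @param geneset Character vector of set genes.
#' @param n_perm Number of permutations (\eqn{\ge 100}).
#' @param scheme \code{"phenotype"} or \code{"geneset"}.
#' @param seed Integer seed; results are deterministic given it.
#' @param metric Ranking metric, see [rank_by_groups()].
#' @param weight ES weight exponent.
#' @return List of class \code{"enrichment_result"}: \code{set_size_used},
#'   \code{ES}, \code{NES}, \code{nominal_p}, \code{n_perm},
#'   \code{leading_edge}.
#' @export
permutation_test <- function(expr, labels, geneset, n_perm = 1000L,
                             scheme = c("phenotype", "geneset"), seed = 1L,
                             metric = "signal2noise", weight = 1) {
  scheme <- match.arg(scheme)
  if (n_perm < 100L) stop("n_perm must be at least 100")
  labels <- droplevels(factor(labels))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  ranked <- rank_by_groups(expr, labels, metric = metric)
  obs <- enrichment_score(ranked, geneset, weight = weight)
  set_size <- sum(names(ranked) %in% geneset)

  null_es <- numeric(n_perm)
  if (scheme == "phenotype") {
    for (b in seq_len(n_perm)) {
      perm <- sample(labels)
      if (min(table(perm)) < 3L) stop("degenerate permutation: a group emptied")
      r <- rank_by_groups(expr, perm, metric = metric)
      null_es[b] <- enrichment_score(r, geneset, weight = weight)$ES
    }
  } else {
    universe <- names(ranked)
    for (b in seq_len(n_perm)) {
      rs <- sample(universe, set_size)
      null_es[b] <- enrichment_score(ranked, rs, weight = weight)$ES
    }
  }
  same_sign <- null_es[sign(null_es) == sign(obs$ES)]
  nes <- if (length(same_sign) > 0L) obs$ES / mean(abs(same_sign)) else NA_real_
  p <- (1 + sum(abs(null_es) >= abs(obs$ES))) / (n_perm + 1)
  structure(list(set_size_used = set_size, ES = obs$ES, NES = nes,
                 nominal_p = p, n_perm = n_perm,
                 leading_edge = obs$leading_edge, scheme = scheme),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("GSEA (%s permutation, n=%d): ES = %.3f, NES = %.3f, p = %.4g\n",
              x$scheme, x$n_perm, x$ES, x$NES, x$nominal_p))
  cat(sprintf("  set genes used: %d; leading edge: %d genes\n",
              x$set_size_used, length(x$leading_edge)))
  invisible(x)
}

#' Methylation-expression correlation classifier
#'
#' Pearson correlation, per gene, between DNA methylation score and
#' expression across shared samples (pairwise-complete observations). Genes
#' whose correlation falls below \code{threshold} (a high inverse
#' correlation, e.g. \eqn{r < -0.50}) are flagged as candidates for
#' methylation-driven silencing. Genes with fewer than 3 complete pairs are
#' skipped with a warning.
#'
#' @param meth Genes-by-samples methylation matrix (values in \eqn{[0,1]}).
#' @param expr Genes-by-samples expression matrix.
#' @param genes Genes to test (present in both matrices).
#' @param threshold Flagging threshold on r (default -0.50).
#' @return Data frame with columns \code{gene}, \code{pearson_r},
#'   \code{n_pairs}, \code{flagged}.
#' @export
meth_expr_correlation <- function(meth, expr, genes, threshold = -0.50) {
  samples <- intersect(colnames(meth), colnames(expr))
  if (length(samples) < 3L) stop("fewer than 3 shared samples")
  genes_ok <- intersect(genes, intersect(rownames(meth), rownames(expr)))
  if (length(genes_ok) == 0L) stop("no requested gene present in both matrices")
  rows <- lapply(genes_ok, function(g) {
    m <- meth[g, samples]; x <- expr[g, samples]
    keep <- !is.na(m) & !is.na(x)
    if (sum(keep) < 3L) {
      warning("gene ", g, " skipped: fewer than 3 complete pairs")
      return(NULL)
    }
    r <- suppressWarnings(stats::cor(m[keep], x[keep]))
    if (is.na(r)) {
      warning("gene ", g, " skipped: zero variance")
      return(NULL)
    }
    data.frame(gene = g, pearson_r = r, n_pairs = sum(keep),
               flagged = r < threshold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene with enough complete pairs")
  rownames(out) <- NULL
  out
}
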