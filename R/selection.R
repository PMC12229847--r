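#' One-way ANOVA with monotone-trend call across aggressiveness tertiles
#'
#' For every gene, the classic one-way ANOVA F statistic across the three
#' tertile groups, plus a trend call: \code{up} if the low, intermediate and
#' high group means strictly increase, \code{down} if they strictly
#' decrease, \code{none} otherwise. The trend operationalizes "consistent
#' up- or downregulation across increasing tumor aggressiveness".
#'
#' @param expr Genes-by-samples matrix.
#' @param tertiles Factor with levels \code{low}, \code{intermediate},
#'   \code{high}, aligned to the columns of \code{expr}.
#' @return Data frame with columns \code{gene}, \code{mean_low},
#'   \code{mean_intermediate}, \code{mean_high}, \code{F}, \code{p},
#'   \code{trend}.
#' @export
anova_trend <- function(expr, tertiles) {
  stopifnot(is.matrix(expr), ncol(expr) == length(tertiles))
  tertiles <- factor(tertiles, levels = c("low", "intermediate", "high"))
  ng <- table(tertiles)
  if (any(ng == 0L)) stop("empty tertile group")
  n <- ncol(expr)
  k <- 3L
  gm <- vapply(levels(tertiles),
               function(l) rowMeans(expr[, tertiles == l, drop = FALSE]),
               numeric(nrow(expr)))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1L,
                                     dimnames = list(rownames(expr), levels(tertiles)))
  grand <- rowMeans(expr)
  ssb <- as.vector((gm - grand)^2 %*% as.vector(ng))
  sst <- rowSums((expr - grand)^2)
  ssw <- sst - ssb
  Fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(Fstat, k - 1, n - k, lower.tail = FALSE)
  trend <- rep("none", nrow(expr))
  trend[gm[, 1L] < gm[, 2L] & gm[, 2L] < gm[, 3L]] <- "up"
  trend[gm[, 1L] > gm[, 2L] & gm[, 2L] > gm[, 3L]] <- "down"
  data.frame(gene = rownames(expr), mean_low = gm[, 1L],
             mean_intermediate = gm[, 2L], mean_high = gm[, 3L],
             F = Fstat, p = p, trend = trend,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tukey HSD post hoc comparisons for selected genes
#'
#' Pairwise Tukey honest-significant-difference p-values across the tertile
#' groups, reported alongside the ANOVA (it is not a selection gate).
#'
#' @param expr Genes-by-samples matrix.
#' @param tertiles Tertile factor aligned to columns.
#' @param genes Genes to test (default: all rows).
#' @return Data frame with one row per gene and pairwise adjusted p-values.
#' @export
tukey_posthoc <- function(expr, tertiles, genes = rownames(expr)) {
  genes <- intersect(genes, rownames(expr))
  tertiles <- factor(tertiles, levels = c("low", "intermediate", "high"))
  rows <- lapply(genes, function(g) {
    fit <- stats::aov(expr[g, ] ~ tertiles)
    tk <- stats::TukeyHSD(fit)$tertiles
    data.frame(gene = g,
               p_int_vs_low = tk["intermediate-low", "p adj"],
               p_high_vs_low = tk["high-low", "p adj"],
               p_high_vs_int = tk["high-intermediate", "p adj"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-gene two-group Student's t-test with BH correction
#'
#' Classic (equal-variance) two-sample t-test per gene, vectorized over
#' genes; q-values are Benjamini-Hochberg over the whole tested family.
#'
#' @param expr Genes-by-samples matrix.
#' @param labels Two-level factor aligned to columns; the t statistic is
#'   mean(second level) - mean(first level).
#' @return Data frame with columns \code{gene}, \code{diff}, \code{t},
#'   \code{p}, \code{q}.
#' @export
two_group_test <- function(expr, labels) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2L) stop("two_group_test needs exactly two groups")
  n1 <- sum(labels == levels(labels)[1L])
  n2 <- sum(labels == levels(labels)[2L])
  if (min(n1, n2) < 2L) stop("each group needs at least 2 samples")
  x1 <- expr[, labels == levels(labels)[1L], drop = FALSE]
  x2 <- expr[, labels == levels(labels)[2L], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- ifelse(se > 0, (m2 - m1) / se, 0)
  p <- ifelse(se > 0,
              2 * stats::pt(abs(tt), df = n1 + n2 - 2L, lower.tail = FALSE), 1)
  data.frame(gene = rownames(expr), diff = m2 - m1, t = tt, p = p,
             q = bh_fdr(p), stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Validates the input p-values and applies the standard step-up procedure
#' (\code{stats::p.adjust}, method \code{"BH"}):
#' \eqn{q_i = \min_{j: p_j \ge p_i} m p_j / \mathrm{rank}_j}, capped at 1.
#'
#' @param pvalues Numeric vector of p-values in \eqn{[0, 1]}.
#' @return Vector of q-values, monotone in p.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Three-criteria selection of differentially expressed metabolic targets
#'
#' A metabolic gene is selected iff it (a) shows a strictly monotone trend
#' across the low/intermediate/high aggressiveness tertiles with an ANOVA
#' BH q below \code{fdr}; (b) is differentially expressed between early- and
#' advanced-stage tumors (BH q below \code{fdr}) with the stage direction
#' concordant with the trend; and (c) has an optimal-cutpoint log-rank
#' survival association with p below \code{surv_alpha}. FDR correction is
#' applied separately to the ANOVA and stage families. Up-trending selected
#' genes are reported as oncogenic candidates, down-trending as suppressor
#' candidates.
#'
#' @param expr Genes-by-samples expression matrix.
#' @param metab_genes Metabolic catalog (genes outside \code{expr} are
#'   dropped with a warning).
#' @param tertiles Aggressiveness tertile factor aligned to columns.
#' @param stage Factor with levels \code{early}, \code{advanced} aligned to
#'   columns (samples with missing stage excluded beforehand).
#' @param clinical Data frame with \code{sample_id}, \code{time},
#'   \code{event}; samples lacking survival data are omitted from the
#'   survival criterion.
#' @param fdr BH q threshold for the ANOVA and stage families.
#' @param surv_alpha Raw p threshold for the survival criterion.
#' @param min_frac Minimum group fraction for the cutpoint scan.
#' @return A list of class \code{"selection_result"}: \code{table} (per-gene
#'   statistics), \code{selected_up}, \code{selected_down},
#'   \code{thresholds}.
#' @export
select_targets <- function(expr, metab_genes, tertiles, stage, clinical,
                           fdr = 0.05, surv_alpha = 0.05, min_frac = 0.1) {
  missing_genes <- setdiff(metab_genes, rownames(expr))
  if (length(missing_genes) > 0L)
    warning(length(missing_genes), " catalog gene(s) absent from expression matrix")
  genes <- intersect(metab_genes, rownames(expr))
  if (length(genes) == 0L) stop("metabolic catalog empty after intersection")
  sub <- expr[genes, , drop = FALSE]

  av <- anova_trend(sub, tertiles)
  av$q <- bh_fdr(av$p)

  stage <- factor(stage, levels = c("early", "advanced"))
  st <- two_group_test(sub, stage)   # t > 0 means higher in advanced

  sd <- align_survival(stats::setNames(rep(0, ncol(sub)), colnames(sub)),
                       clinical)
  sv <- gene_survival_scan(sub[, sd$sample_ids, drop = FALSE],
                           sd$time, sd$event, min_frac = min_frac)

  trend_ok <- av$trend != "none" & av$q < fdr
  concordant <- (av$trend == "up" & st$t > 0) | (av$trend == "down" & st$t < 0)
  stage_ok <- st$q < fdr & concordant
  surv_ok <- !sv$flagged & !is.na(sv$p) & sv$p < surv_alpha
  selected <- trend_ok & stage_ok & surv_ok

  tab <- data.frame(gene = av$gene,
                    mean_low = av$mean_low,
                    mean_intermediate = av$mean_intermediate,
                    mean_high = av$mean_high,
                    anova_F = av$F, anova_p = av$p, anova_q = av$q,
                    trend = av$trend,
                    stage_t = st$t, stage_p = st$p, stage_q = st$q,
                    surv_p = sv$p, surv_direction = sv$direction,
                    selected = selected, stringsAsFactors = FALSE)
  structure(list(table = tab,
                 selected_up = tab$gene[selected & tab$trend == "up"],
                 selected_down = tab$gene[selected & tab$trend == "down"],
                 thresholds = list(fdr = fdr, surv_alpha = surv_alpha,
                                   min_frac = min_frac)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Differential metabolic target selection: %d of %d genes\n",
              sum(x$table$selected), nrow(x$table)))
  cat(sprintf("  up (oncogenic candidates):   %d\n", length(x$selected_up)))
  cat(sprintf("  down (suppressor candidates): %d\n", length(x$selected_down)))
  cat(sprintf("  thresholds: FDR < %g (ANOVA and stage), survival p < %g\n",
              x$thresholds$fdr, x$thresholds$surv_alpha))
  invisible(x)
}
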