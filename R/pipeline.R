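#' Discover a signed metabolic gene signature from a tumor cohort
#'
#' The full discovery analysis, end to end: row Z-scoring; EMT
#' aggressiveness score (sum of Z-scores over the EMT program) and tertile
#' stratification; three-criteria selection of differentially expressed
#' metabolic targets (monotone tertile trend + stage differential expression
#' + optimal-cutpoint survival association); interaction network induced on
#' the selected targets; random-walk energy diffusion and hub selection at
#' an RW score of at least \code{rw_threshold}; a signed signature (hubs
#' with an up trend are oncogenic, down trend suppressor) scored per sample
#' as sum(up Z) - sum(down Z); optimal-cutpoint survival split of that
#' score; gene-set enrichment between the low/high signature groups; and,
#' when methylation is supplied, the methylation-expression correlation
#' classification of the signature genes.
#'
#' @param expr Genes-by-samples log-scale expression matrix.
#' @param clinical Data frame with \code{sample_id}, \code{stage},
#'   \code{time}, \code{event} (see [read_clinical()]).
#' @param edges Canonical interaction edge list (see [read_edges()]).
#' @param emt_genes EMT program gene ids (the aggressiveness score set).
#' @param metab_genes Metabolic catalog gene ids.
#' @param methylation Optional genes-by-samples methylation matrix.
#' @param gsea_sets Optional named list of gene sets to test between the
#'   low/high signature groups (default: the EMT program).
#' @param fdr BH q threshold of the selection filter.
#' @param surv_alpha Survival p threshold of the selection filter.
#' @param rw_threshold Inclusive RW-score hub cutoff.
#' @param corr_threshold Methylation-expression flagging threshold.
#' @param min_score Optional minimum interaction score for edges.
#' @param min_frac Minimum group fraction of the cutpoint scans.
#' @param n_perm GSEA permutations.
#' @param seed Seed for the GSEA permutations.
#' @return An object of class \code{"metab_discovery"}; see
#'   [print.metab_discovery()], [summary.metab_discovery()],
#'   [run_report()].
#' @export
discover_signature <- function(expr, clinical, edges, emt_genes, metab_genes,
                               methylation = NULL, gsea_sets = NULL,
                               fdr = 0.05, surv_alpha = 0.05,
                               rw_threshold = 2.0, corr_threshold = -0.50,
                               min_score = NULL, min_frac = 0.1,
                               n_perm = 200L, seed = 1L) {
  stage_name <- "input checks"
  res <- tryCatch({
    stopifnot(is.matrix(expr))
    samples <- intersect(colnames(expr), clinical$sample_id)
    if (length(samples) < 10L) stop("fewer than 10 samples shared by expression and clinical")
    expr <- expr[, samples, drop = FALSE]
    cl <- clinical[match(samples, clinical$sample_id), , drop = FALSE]
    if (!is.null(min_score)) edges <- edges[edges$score >= min_score, , drop = FALSE]

    stage_name <- "z-scoring"
    z <- zscore_rows(expr)

    stage_name <- "EMT aggressiveness score"
    emt_score <- geneset_score(z, emt_genes)

    stage_name <- "tertile stratification"
    tertiles <- tertile_groups(emt_score)

    stage_name <- "target selection"
    stage <- factor(cl$stage, levels = c("early", "advanced"))
    if (any(is.na(stage))) {
      keep <- !is.na(stage)
      sel <- select_targets(z[, keep, drop = FALSE], metab_genes,
                            tertiles[keep], stage[keep], cl,
                            fdr = fdr, surv_alpha = surv_alpha,
                            min_frac = min_frac)
    } else {
      sel <- select_targets(z, metab_genes, tertiles, stage, cl,
                            fdr = fdr, surv_alpha = surv_alpha,
                            min_frac = min_frac)
    }
    selected <- c(sel$selected_up, sel$selected_down)
    if (length(selected) == 0L) {
      return(empty_discovery(sel, tertiles, emt_score,
                             list(fdr = fdr, surv_alpha = surv_alpha,
                                  rw_threshold = rw_threshold,
                                  corr_threshold = corr_threshold,
                                  min_frac = min_frac, n_perm = n_perm,
                                  seed = seed)))
    }

    stage_name <- "network construction"
    net <- tryCatch(build_network(edges, restrict_to = selected),
                    error = function(e) NULL)

    walk <- NULL; hubs <- character(0)
    if (!is.null(net)) {
      stage_name <- "random walk"
      walk <- random_walk_scores(net)
      stage_name <- "hub selection"
      hubs <- select_hubs(walk, threshold = rw_threshold)
    }
    sig_up <- intersect(hubs, sel$selected_up)
    sig_down <- intersect(hubs, sel$selected_down)

    sig_score <- NULL; sig_groups <- NULL; sig_surv <- NULL
    gsea <- NULL; methcorr <- NULL
    if (length(c(sig_up, sig_down)) > 0L) {
      stage_name <- "signature scoring"
      sig_score <- signed_signature_score(z, sig_up, sig_down)

      stage_name <- "signature survival"
      sd <- align_survival(sig_score, cl)
      if (length(unique(sd$score)) >= 2L) {
        cut <- optimal_cutoff(sd$score, sd$time, sd$event, min_frac = min_frac)
        sig_groups <- factor(ifelse(sig_score > cut$cutpoint, "high", "low"),
                             levels = c("low", "high"))
        names(sig_groups) <- names(sig_score)
        sig_surv <- cut
      }

      if (!is.null(sig_groups) && min(table(sig_groups)) >= 3L) {
        stage_name <- "GSEA"
        if (is.null(gsea_sets)) gsea_sets <- list(EMT_program = emt_genes)
        gsea <- lapply(gsea_sets, function(gs)
          tryCatch(permutation_test(z, sig_groups, gs, n_perm = n_perm,
                                    seed = seed),
                   error = function(e) NULL))
      }

      if (!is.null(methylation)) {
        stage_name <- "methylation correlation"
        methcorr <- tryCatch(
          meth_expr_correlation(methylation, expr, c(sig_up, sig_down),
                                threshold = corr_threshold),
          error = function(e) NULL)
      }
    }

    structure(list(selection = sel,
                   emt_score = emt_score, tertiles = tertiles,
                   network = net, walk = walk, hubs = hubs,
                   signature_up = sig_up, signature_down = sig_down,
                   signature_score = sig_score,
                   signature_groups = sig_groups,
                   signature_survival = sig_surv,
                   gsea = gsea, methcorr = methcorr,
                   clinical = cl,
                   thresholds = list(fdr = fdr, surv_alpha = surv_alpha,
                                     rw_threshold = rw_threshold,
                                     corr_threshold = corr_threshold,
                                     min_frac = min_frac, n_perm = n_perm,
                                     seed = seed)),
              class = "metab_discovery")
  }, error = function(e) {
    stop("discovery failed at stage '", stage_name, "': ",
         conditionMessage(e), call. = FALSE)
  })
  res
}

empty_discovery <- function(sel, tertiles, emt_score, thresholds) {
  structure(list(selection = sel, emt_score = emt_score, tertiles = tertiles,
                 network = NULL, walk = NULL, hubs = character(0),
                 signature_up = character(0), signature_down = character(0),
                 signature_score = NULL, signature_groups = NULL,
                 signature_survival = NULL, gsea = NULL, methcorr = NULL,
                 clinical = NULL, thresholds = thresholds),
            class = "metab_discovery")
}

#' Validate a fixed signed signature on an independent cohort
#'
#' Computes the signed signature score on a new cohort (no re-selection) and
#' associates it with stage, grade, any binary outcome columns, and survival
#' (optimal-cutpoint log-rank). At least half of the signature genes must be
#' measured for the score to be comparable.
#'
#' @param expr Genes-by-samples expression matrix of the validation cohort.
#' @param clinical Clinical table of the validation cohort.
#' @param signature_up,signature_down The fixed signature gene lists.
#' @param min_frac Minimum group fraction for the cutpoint scan.
#' @return An object of class \code{"metab_validation"}: the per-sample
#'   score, a table of score-vs-outcome t-tests, and the survival cutpoint
#'   result.
#' @export
validate_signature <- function(expr, clinical, signature_up,
                               signature_down = character(0),
                               min_frac = 0.1) {
  sig <- c(signature_up, signature_down)
  present <- intersect(sig, rownames(expr))
  if (length(present) < 0.5 * length(sig))
    stop("fewer than 50% of signature genes present: score not comparable")
  samples <- intersect(colnames(expr), clinical$sample_id)
  expr <- expr[, samples, drop = FALSE]
  cl <- clinical[match(samples, clinical$sample_id), , drop = FALSE]
  z <- zscore_rows(expr)
  score <- signed_signature_score(z, intersect(signature_up, rownames(z)),
                                  intersect(signature_down, rownames(z)))

  assoc <- list()
  two_level <- function(v, lev) factor(v, levels = lev)
  outcomes <- list()
  if ("stage" %in% colnames(cl))
    outcomes$stage <- two_level(cl$stage, c("early", "advanced"))
  if ("grade" %in% colnames(cl))
    outcomes$grade <- two_level(cl$grade, c("low", "high"))
  for (col in setdiff(colnames(cl), c("sample_id", "stage", "grade",
                                      "time", "event"))) {
    v <- cl[[col]]
    if (all(v %in% c(0, 1, NA))) outcomes[[col]] <- factor(v, levels = c(0, 1))
  }
  for (nm in names(outcomes)) {
    g <- outcomes[[nm]]
    keep <- !is.na(g)
    if (min(table(g[keep])) < 2L) next
    tt <- stats::t.test(score[keep] ~ g[keep], var.equal = TRUE)
    assoc[[nm]] <- data.frame(outcome = nm,
                              mean_low = tt$estimate[[1L]],
                              mean_high = tt$estimate[[2L]],
                              t = -tt$statistic[[1L]],
                              p = tt$p.value, stringsAsFactors = FALSE)
  }
  assoc <- do.call(rbind, assoc)
  if (!is.null(assoc)) rownames(assoc) <- NULL

  surv <- NULL
  if (all(c("time", "event") %in% colnames(cl))) {
    sd <- align_survival(score, cl)
    surv <- tryCatch(optimal_cutoff(sd$score, sd$time, sd$event,
                                    min_frac = min_frac),
                     error = function(e) NULL)
  }
  structure(list(score = score, associations = assoc, survival = surv,
                 signature_up = signature_up, signature_down = signature_down,
                 genes_used = present),
            class = "metab_validation")
}

#' @export
print.metab_discovery <- function(x, ...) {
  cat("Metabolic signature discovery\n")
  cat(sprintf("  catalog genes tested:   %d\n", nrow(x$selection$table)))
  cat(sprintf("  selected targets:       %d (%d up, %d down)\n",
              length(c(x$selection$selected_up, x$selection$selected_down)),
              length(x$selection$selected_up), length(x$selection$selected_down)))
  if (!is.null(x$network))
    cat(sprintf("  network:                %d nodes, %d edges (%d isolated removed)\n",
                length(x$network$nodes), x$network$n_edges,
                length(x$network$isolated)))
  cat(sprintf("  hubs (RW score >= %g):  %d\n", x$thresholds$rw_threshold,
              length(x$hubs)))
  if (length(c(x$signature_up, x$signature_down)) > 0L) {
    cat("  signature up (oncogenic):  ",
        paste(x$signature_up, collapse = ", "), "\n")
    cat("  signature down (suppressor):",
        paste(x$signature_down, collapse = ", "), "\n")
    if (!is.null(x$signature_survival))
      cat(sprintf("  signature log-rank: chi2 = %.3g, p = %.3g (%s)\n",
                  x$signature_survival$chi2, x$signature_survival$p,
                  x$signature_survival$direction))
  } else {
    cat("  signature: empty\n")
  }
  invisible(x)
}

#' @rdname print.metab_discovery
#' @param object,x A \code{metab_discovery} object.
#' @param ... Unused.
#' @export
summary.metab_discovery <- function(object, ...) {
  print(object)
  if (!is.null(object$walk)) {
    cat("\nRW scores of hubs:\n")
    print(round(sort(object$walk$rw_score[object$hubs], decreasing = TRUE), 3))
  }
  if (!is.null(object$methcorr)) {
    cat("\nMethylation-expression correlation of signature genes:\n")
    print(object$methcorr)
  }
  if (!is.null(object$gsea)) {
    cat("\nGSEA between signature-low and signature-high groups:\n")
    for (nm in names(object$gsea)) {
      g <- object$gsea[[nm]]
      if (!is.null(g))
        cat(sprintf("  %s: NES = %.3f, p = %.4g\n", nm, g$NES, g$nominal_p))
    }
  }
  invisible(object)
}

#' Kaplan-Meier plot of the signature groups
#'
#' @param x A \code{metab_discovery} object with a non-empty signature.
#' @param ... Passed to \code{plot.survfit}.
#' @export
plot.metab_discovery <- function(x, ...) {
  if (is.null(x$signature_groups)) stop("no signature groups to plot")
  sd <- align_survival(x$signature_score, x$clinical)
  g <- x$signature_groups[sd$sample_ids]
  fit <- survival::survfit(survival::Surv(sd$time, sd$event) ~ g)
  graphics::plot(fit, col = c("forestgreen", "firebrick"),
                 xlab = "Time", ylab = "Survival probability", ...)
  graphics::legend("topright", legend = c("signature low", "signature high"),
                   col = c("forestgreen", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' @export
print.metab_validation <- function(x, ...) {
  cat(sprintf("Signature validation (%d/%d signature genes measured)\n",
              length(x$genes_used),
              length(c(x$signature_up, x$signature_down))))
  if (!is.null(x$associations)) print(x$associations)
  if (!is.null(x$survival))
    cat(sprintf("  survival: log-rank chi2 = %.3g, p = %.3g (%s)\n",
                x$survival$chi2, x$survival$p, x$survival$direction))
  invisible(x)
}

#' Machine-readable run report
#'
#' Collapses a discovery fit into a list of stage counts, the signed
#' signature, per-sample scores and groups, survival and enrichment
#' summaries, and the thresholds applied — ready for JSON serialization.
#'
#' @param fit A \code{metab_discovery} object.
#' @return A named list; write it with [write_run_report()].
#' @export
run_report <- function(fit) {
  stopifnot(inherits(fit, "metab_discovery"))
  list(
    counts = list(
      catalog = nrow(fit$selection$table),
      pass_trend = sum(fit$selection$table$trend != "none" &
                         fit$selection$table$anova_q < fit$thresholds$fdr),
      pass_stage = sum(fit$selection$table$stage_q < fit$thresholds$fdr),
      pass_survival = sum(!is.na(fit$selection$table$surv_p) &
                            fit$selection$table$surv_p < fit$thresholds$surv_alpha),
      selected = sum(fit$selection$table$selected),
      network_nodes = if (is.null(fit$network)) 0L else length(fit$network$nodes),
      isolated = if (is.null(fit$network)) 0L else length(fit$network$isolated),
      hubs = length(fit$hubs)),
    signature = list(up = as.list(fit$signature_up),
                     down = as.list(fit$signature_down)),
    scores = if (is.null(fit$signature_score)) NULL else
      list(sample_id = names(fit$signature_score),
           score = unname(fit$signature_score),
           group = as.character(fit$signature_groups)),
    survival = if (is.null(fit$signature_survival)) NULL else
      fit$signature_survival[c("cutpoint", "chi2", "p", "n_low", "n_high",
                               "direction")],
    gsea = if (is.null(fit$gsea)) NULL else
      lapply(fit$gsea, function(g) if (is.null(g)) NULL else
        g[c("ES", "NES", "nominal_p", "n_perm")]),
    methylation = if (is.null(fit$methcorr)) NULL else
      list(gene = fit$methcorr$gene, pearson_r = fit$methcorr$pearson_r,
           flagged = fit$methcorr$flagged),
    thresholds = fit$thresholds)
}

#' Write a run report as JSON
#'
#' @param fit A \code{metab_discovery} object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_run_report <- function(fit, path) {
  jsonlite::write_json(run_report(fit), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
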