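#' Row-wise Z-scoring of an expression matrix
#'
#' Centers and scales every gene row to mean 0 and sample standard deviation
#' 1 (denominator \eqn{n-1}). Zero-variance rows carry no cohort information
#' and are dropped with a warning.
#'
#' @param expr Numeric genes-by-samples matrix (at least 2 samples).
#' @return The Z-scored matrix, possibly with fewer rows.
#' @export
zscore_rows <- function(expr) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 2L) stop("zscore_rows needs at least 2 samples")
  mu <- rowMeans(expr)
  sdev <- sqrt(rowSums((expr - mu)^2) / (ncol(expr) - 1L))
  zero <- sdev == 0 | !is.finite(sdev)
  if (all(zero)) stop("all rows have zero variance")
  if (any(zero))
    warning(sum(zero), " zero-variance row(s) dropped: ",
            paste(utils::head(rownames(expr)[zero], 5L), collapse = ", "))
  (expr[!zero, , drop = FALSE] - mu[!zero]) / sdev[!zero]
}

#' Gene-set score: per-sample sum of Z-scores
#'
#' The aggregation used both for the EMT aggressiveness score (sum over the
#' 200-gene hallmark EMT program) and for complex-activity scores: for each
#' sample, the sum of the row Z-scores of the set genes present in the
#' matrix. Set genes absent from the matrix reduce the sum and are counted,
#' not imputed.
#'
#' @param zexpr Row-Z-scored matrix (see [zscore_rows()]).
#' @param geneset Character vector of gene ids.
#' @return Named numeric vector (one score per sample) with attributes
#'   \code{n_genes_used} and \code{n_missing}.
#' @export
geneset_score <- function(zexpr, geneset) {
  geneset <- unique(geneset)
  present <- intersect(geneset, rownames(zexpr))
  if (length(present) == 0L) stop("no gene of the set is present in the matrix")
  s <- colSums(zexpr[present, , drop = FALSE])
  attr(s, "n_genes_used") <- length(present)
  attr(s, "n_missing") <- length(geneset) - length(present)
  s
}

#' Signed signature score (Metab-GS style)
#'
#' Per-sample sum of Z-scores of the up (oncogenic) set minus the sum over
#' the down (tumor-suppressor) set. With the seven-gene metabolic signature
#' (up = ALDH1B1, ALDH1L2, CHSY1, CSGALNACT2, GPX8; down = FBP1, HPGD) this
#' is the Metab-GS score.
#'
#' @param zexpr Row-Z-scored matrix.
#' @param up_set,down_set Disjoint character vectors; \code{down_set} may be
#'   empty.
#' @return Named numeric vector of per-sample scores.
#' @export
signed_signature_score <- function(zexpr, up_set, down_set = character(0)) {
  if (length(intersect(up_set, down_set)) > 0L)
    stop("up_set and down_set overlap: ",
         paste(intersect(up_set, down_set), collapse = ", "))
  up <- if (length(up_set) > 0L) geneset_score(zexpr, up_set) else
    stats::setNames(rep(0, ncol(zexpr)), colnames(zexpr))
  dn <- if (length(down_set) > 0L) geneset_score(zexpr, down_set) else
    stats::setNames(rep(0, ncol(zexpr)), colnames(zexpr))
  s <- as.numeric(up) - as.numeric(dn)
  names(s) <- colnames(zexpr)
  s
}

#' Tertile stratification of a per-sample score
#'
#' Ranks samples ascending by score and splits them into low / intermediate /
#' high groups whose sizes differ by at most one; when \eqn{n} is not
#' divisible by 3 the extra samples go to the lower groups first
#' (n = 10 gives 4/3/3). Score ties are broken by sample-id order, so the
#' labelling is deterministic.
#'
#' @param score Named numeric vector (names are sample ids).
#' @return Factor with levels \code{low}, \code{intermediate}, \code{high},
#'   named by sample id.
#' @export
tertile_groups <- function(score) {
  n <- length(score)
  if (n < 3L) stop("tertile split needs at least 3 samples")
  if (is.null(names(score))) names(score) <- as.character(seq_len(n))
  ord <- order(score, names(score))
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- base + c(rem >= 1L, rem >= 2L, 0L)
  lab <- rep(c("low", "intermediate", "high"), times = sizes)
  out <- factor(character(n), levels = c("low", "intermediate", "high"))
  out[ord] <- lab
  names(out) <- names(score)
  out
}

#' Two-group split of a per-sample score
#'
#' \code{median}: a sample is \code{high} iff its score exceeds the cohort
#' median. \code{optimal_survival}: the cutpoint minimizing the log-rank
#' p-value over all admissible splits (see [optimal_cutoff()]), which
#' requires survival annotations.
#'
#' @param score Named numeric vector.
#' @param method \code{"median"} or \code{"optimal_survival"}.
#' @param clinical Data frame with \code{sample_id}, \code{time},
#'   \code{event} (needed for \code{optimal_survival}).
#' @param min_frac Minimum group fraction for the optimal scan.
#' @return Factor with levels \code{low}, \code{high}, named by sample id;
#'   attribute \code{"cutpoint"} holds the threshold used.
#' @export
binary_split <- function(score, method = c("median", "optimal_survival"),
                         clinical = NULL, min_frac = 0.1) {
  method <- match.arg(method)
  if (length(unique(score)) < 2L) stop("no admissible cutpoint: scores constant")
  if (method == "median") {
    cut <- stats::median(score)
  } else {
    if (is.null(clinical)) stop("optimal_survival split requires a clinical table")
    sd <- align_survival(score, clinical)
    res <- optimal_cutoff(sd$score, sd$time, sd$event, min_frac = min_frac)
    cut <- res$cutpoint
  }
  out <- factor(ifelse(score > cut, "high", "low"), levels = c("low", "high"))
  names(out) <- names(score)
  attr(out, "cutpoint") <- cut
  out
}

# align a named score vector with clinical survival columns, dropping
# samples that lack time or event
align_survival <- function(score, clinical) {
  stopifnot(all(c("sample_id", "time", "event") %in% colnames(clinical)))
  cl <- clinical[!is.na(clinical$time) & !is.na(clinical$event), , drop = FALSE]
  common <- intersect(names(score), cl$sample_id)
  if (length(common) < 2L) stop("fewer than 2 samples with survival data")
  cl <- cl[match(common, cl$sample_id), , drop = FALSE]
  list(score = score[common], time = cl$time, event = cl$event,
       sample_ids = common)
}
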