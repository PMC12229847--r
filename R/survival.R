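#' Kaplan-Meier curves per group
#'
#' Product-limit estimates via \code{survival::survfit}, returned as one
#' tidy step table per group.
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param group Optional factor of group labels (one curve per level).
#' @return Data frame with columns \code{group}, \code{time},
#'   \code{n_risk}, \code{n_event}, \code{n_censor}, \code{surv}.
#' @export
km_curve <- function(time, event, group = NULL) {
  stopifnot(length(time) == length(event), all(time > 0))
  if (is.null(group)) group <- factor(rep("all", length(time)))
  if (!is.factor(group)) group <- factor(group)
  if (any(table(group) == 0L)) stop("empty group in km_curve")
  group <- droplevels(group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  if (is.null(fit$strata)) {
    grp <- rep(levels(group)[1L], length(fit$time))
  } else {
    grp <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, n_censor = fit$n.censor,
             surv = fit$surv, stringsAsFactors = FALSE)
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' Observed-minus-expected events in one group accumulated over event times,
#' with the hypergeometric variance; the statistic is chi-square with 1
#' degree of freedom. Handles tied event times.
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (1/0).
#' @param group Two-level factor (or coercible).
#' @return List with \code{chi2}, \code{p}, \code{obs} and \code{exp}
#'   (events observed/expected in the second level), and \code{direction}
#'   (level name of the group with worse survival, \code{"none"} if no
#'   information).
#' @export
logrank <- function(time, event, group) {
  if (!is.factor(group)) group <- factor(group)
  if (any(table(group) == 0L)) stop("empty group in logrank")
  if (nlevels(group) != 2L) stop("logrank needs exactly two groups")
  stopifnot(length(time) == length(event), length(time) == length(group))
  h <- group == levels(group)[2L]
  st <- .logrank_stat(time, event, h)
  direction <- if (st$v <= 0 || st$o == st$e) "none"
  else if (st$o > st$e) levels(group)[2L] else levels(group)[1L]
  chi2 <- if (st$v > 0) (st$o - st$e)^2 / st$v else 0
  list(chi2 = chi2,
       p = if (st$v > 0) stats::pchisq(chi2, df = 1, lower.tail = FALSE) else 1,
       obs = st$o, exp = st$e, direction = direction)
}

# core O/E/V accumulation for a logical group indicator h
.logrank_stat <- function(time, event, h) {
  et <- sort(unique(time[event == 1]))
  if (length(et) == 0L) return(list(o = 0, e = 0, v = 0))
  o <- e <- v <- 0
  for (t in et) {
    at <- time >= t
    N <- sum(at)
    d <- sum(event == 1 & time == t)
    n1 <- sum(at & h)
    d1 <- sum(event == 1 & time == t & h)
    o <- o + d1
    e <- e + d * n1 / N
    if (N > 1L) v <- v + d * (n1 / N) * (1 - n1 / N) * (N - d) / (N - 1)
  }
  list(o = o, e = e, v = v)
}

# Precompute the fixed (score-independent) pieces of the cutpoint scan:
# event times, their total event counts and at-risk sizes, the per-event-time
# weights of the O/E/V sums, and the n x T at-risk indicator matrix B
# (B[i, t] = 1 iff sample i is still at risk at event time t).
.scan_prep <- function(time, event) {
  n <- length(time)
  et <- sort(unique(time[event == 1]))
  TT <- length(et)
  if (TT == 0L) return(NULL)
  Nt <- vapply(et, function(t) sum(time >= t), 0)
  dt <- vapply(et, function(t) sum(event == 1 & time == t), 0)
  at <- dt * (Nt - dt) / pmax(Nt - 1, 1)
  at[Nt <= 1] <- 0
  B <- outer(time, et, ">=") * 1
  list(n = n, et = et, Nt = Nt, dt = dt, D = sum(dt),
       w_e = dt / Nt, w_v1 = at / Nt, w_v2 = at / Nt^2, B = B)
}

# chi2 and p for every low-group size k (1..n-1) when samples are taken in
# the order `ord` (ascending score). Vectorized over k: with c(k, t) the
# number of the k lowest-score samples at risk at event time t,
#   O1(k) = D - (events among the k lowest)
#   E1(k) = sum_t d_t - sum_t (d_t/N_t) c(k, t)
#   V(k)  = sum_t a_t c~(k,t)(N_t - c~)/N_t^2   with c~ counted on either side
.logrank_scan <- function(prep, ord, event) {
  n <- prep$n
  CB <- apply(prep$B[ord, , drop = FALSE], 2L, cumsum)      # n x T
  if (is.null(dim(CB))) CB <- matrix(CB, nrow = n)
  cum_ev <- cumsum(event[ord])
  O1 <- prep$D - cum_ev
  E1 <- sum(prep$dt) - as.vector(CB %*% prep$w_e)
  V <- as.vector(CB %*% prep$w_v1) - as.vector((CB * CB) %*% prep$w_v2)
  k <- seq_len(n - 1L)
  O1 <- O1[k]; E1 <- E1[k]; V <- V[k]
  chi2 <- ifelse(V > 1e-12, (O1 - E1)^2 / V, 0)
  p <- ifelse(V > 1e-12, stats::pchisq(chi2, df = 1, lower.tail = FALSE), 1)
  list(k = k, chi2 = chi2, p = p, oe = O1 - E1)
}

#' Optimal survival cutpoint (maximally selected log-rank statistic)
#'
#' Evaluates the two-group log-rank test at every midpoint between
#' consecutive distinct sorted score values for which both resulting groups
#' hold at least \code{floor(min_frac * n)} samples, and returns the
#' cutpoint with the minimal p-value. Ties on p are broken toward the more
#' balanced split, then toward the smaller cutpoint. The returned p-value is
#' the raw minimum and is optimistic (no correction for the scan); see the
#' package vignette.
#'
#' @param score Numeric per-sample score.
#' @param time,event Aligned survival data (complete cases).
#' @param min_frac Minimum fraction of samples on each side of the split.
#' @return List of class \code{"cutpoint_result"}: \code{cutpoint},
#'   \code{chi2}, \code{p}, \code{n_low}, \code{n_high}, \code{direction}
#'   (\code{"high_worse"}, \code{"low_worse"} or \code{"none"}).
#' @export
optimal_cutoff <- function(score, time, event, min_frac = 0.1) {
  n <- length(score)
  stopifnot(length(time) == n, length(event) == n)
  if (anyNA(score) || anyNA(time) || anyNA(event))
    stop("optimal_cutoff requires complete cases")
  ord <- order(score)
  s_sorted <- score[ord]
  min_n <- max(floor(min_frac * n), 1L)
  k_all <- seq_len(n - 1L)
  admissible <- k_all >= min_n & (n - k_all) >= min_n &
    s_sorted[k_all] < s_sorted[k_all + 1L]
  if (!any(admissible)) stop("no admissible cutpoint")
  prep <- .scan_prep(time, event)
  if (is.null(prep)) stop("no events: log-rank cutpoint scan is undefined")
  scan <- .logrank_scan(prep, ord, event)
  p <- scan$p
  p[!admissible] <- Inf
  best_p <- min(p)
  cand <- which(p == best_p)
  balance <- abs(n - 2 * cand)
  cand <- cand[balance == min(balance)]
  k <- cand[which.min((s_sorted[cand] + s_sorted[cand + 1L]) / 2)]
  cutpoint <- unname((s_sorted[k] + s_sorted[k + 1L]) / 2)
  high <- score > cutpoint
  dir <- .cut_direction(time, event, high, scan$oe[k])
  structure(list(cutpoint = cutpoint, chi2 = scan$chi2[k], p = scan$p[k],
                 n_low = k, n_high = n - k, direction = dir),
            class = "cutpoint_result")
}

# product-limit median survival: first event time where S(t) drops to 0.5
# or below, NA if the curve never gets there
.km_median <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  if (length(et) == 0L) return(NA_real_)
  s <- 1
  for (t in et) {
    N <- sum(time >= t)
    d <- sum(event == 1 & time == t)
    s <- s * (1 - d / N)
    if (s <= 0.5) return(t)
  }
  NA_real_
}

# worse-survival side of a split: compare KM median survival of the two
# groups; when a median is undefined (curve never reaches 0.5), fall back to
# the sign of observed-minus-expected events in the high group.
.cut_direction <- function(time, event, high, oe_high) {
  med_low <- .km_median(time[!high], event[!high])
  med_high <- .km_median(time[high], event[high])
  if (!is.na(med_low) && !is.na(med_high) && med_low != med_high)
    return(if (med_high < med_low) "high_worse" else "low_worse")
  if (oe_high > 0) "high_worse" else if (oe_high < 0) "low_worse" else "none"
}

#' Per-gene optimal-cutpoint survival scan
#'
#' Runs [optimal_cutoff()] on every gene row of an expression matrix. Genes
#' for which no admissible cutpoint exists (e.g. constant rows) are flagged
#' and reported with \code{NA} statistics rather than aborting the scan.
#'
#' @param expr Genes-by-samples matrix whose columns align with
#'   \code{time}/\code{event}.
#' @param time,event Survival data (complete cases).
#' @param min_frac Minimum group fraction.
#' @return Data frame with columns \code{gene}, \code{cutpoint},
#'   \code{chi2}, \code{p}, \code{n_low}, \code{n_high}, \code{direction}
#'   (\code{high_expr_worse} / \code{high_expr_better} / \code{none}) and
#'   \code{flagged}.
#' @export
gene_survival_scan <- function(expr, time, event, min_frac = 0.1) {
  stopifnot(is.matrix(expr), ncol(expr) == length(time),
            length(time) == length(event))
  prep <- .scan_prep(time, event)
  if (is.null(prep)) stop("no events in survival data")
  n <- ncol(expr)
  min_n <- max(floor(min_frac * n), 1L)
  res <- lapply(seq_len(nrow(expr)), function(i) {
    score <- expr[i, ]
    ord <- order(score)
    s_sorted <- score[ord]
    k_all <- seq_len(n - 1L)
    admissible <- k_all >= min_n & (n - k_all) >= min_n &
      s_sorted[k_all] < s_sorted[k_all + 1L]
    if (!any(admissible) || anyNA(score)) {
      return(data.frame(gene = rownames(expr)[i], cutpoint = NA_real_,
                        chi2 = NA_real_, p = NA_real_, n_low = NA_integer_,
                        n_high = NA_integer_, direction = "none",
                        flagged = TRUE, stringsAsFactors = FALSE))
    }
    scan <- .logrank_scan(prep, ord, event)
    p <- scan$p
    p[!admissible] <- Inf
    cand <- which(p == min(p))
    balance <- abs(n - 2 * cand)
    cand <- cand[balance == min(balance)]
    k <- cand[which.min((s_sorted[cand] + s_sorted[cand + 1L]) / 2)]
    cutpoint <- unname((s_sorted[k] + s_sorted[k + 1L]) / 2)
    dir <- .cut_direction(time, event, score > cutpoint, scan$oe[k])
    data.frame(gene = rownames(expr)[i], cutpoint = cutpoint,
               chi2 = scan$chi2[k], p = scan$p[k], n_low = k,
               n_high = n - k,
               direction = switch(dir, high_worse = "high_expr_worse",
                                  low_worse = "high_expr_better", "none"),
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("Optimal survival cutpoint: %.4g (n_low=%d, n_high=%d)\n",
              x$cutpoint, x$n_low, x$n_high))
  cat(sprintf("Log-rank chi2 = %.4g, p = %.3g, direction: %s\n",
              x$chi2, x$p, x$direction))
  invisible(x)
}
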