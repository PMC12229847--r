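# Independent brute-force oracles used to check the package's statistics.
# Each is written straight from the textbook definition, favouring clarity
# over speed, and shares no code with the implementation.

# Benjamini-Hochberg step-up from the definition:
# q_i = min over j with p_j >= p_i of m * p_j / rank(p_j), capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    js <- which(p >= p[i])
    min(1, min(m * p[js] / r[js]))
  }, 0)
}

# one-way ANOVA F from explicit sums of squares
oracle_anova_F <- function(x, g) {
  g <- factor(g)
  grand <- mean(x)
  ssb <- 0; ssw <- 0
  for (l in levels(g)) {
    xi <- x[g == l]
    ssb <- ssb + length(xi) * (mean(xi) - grand)^2
    ssw <- ssw + sum((xi - mean(xi))^2)
  }
  (ssb / (nlevels(g) - 1)) / (ssw / (length(x) - nlevels(g)))
}

# two-sample pooled-variance t statistic (second level minus first)
oracle_t <- function(x, g) {
  g <- factor(g)
  x1 <- x[g == levels(g)[1]]; x2 <- x[g == levels(g)[2]]
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  (mean(x2) - mean(x1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# GSEA running sum straight from the definition
oracle_running_sum <- function(ranked, geneset, weight = 0) {
  N <- length(ranked)
  hits <- names(ranked) %in% geneset
  nr <- sum(abs(ranked[hits])^weight)
  run <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    acc <- if (hits[i]) acc + abs(ranked[i])^weight / nr
    else acc - 1 / (N - sum(hits))
    run[i] <- acc
  }
  run
}

# exhaustive minimum-p cutpoint via survival::survdiff at every admissible
# midpoint between consecutive distinct sorted scores
oracle_optimal_cutoff <- function(score, time, event, min_frac = 0.1) {
  n <- length(score)
  s <- sort(score)
  mids <- unique((s[-n] + s[-1])[s[-n] < s[-1]] / 2)
  min_n <- max(floor(min_frac * n), 1)
  best <- NULL
  for (cut in mids) {
    high <- score > cut
    if (sum(high) < min_n || sum(!high) < min_n) next
    sd <- survival::survdiff(survival::Surv(time, event) ~ high)
    p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    if (is.null(best) || p < best$p) best <- list(cutpoint = cut, p = p,
                                                  chi2 = sd$chisq)
  }
  best
}

# small reproducible survival dataset
make_surv <- function(n, seed = 1, beta = 0, score = NULL) {
  set.seed(seed)
  if (is.null(score)) score <- rnorm(n)
  time <- rexp(n, rate = 0.05 * exp(beta * score))
  event <- rbinom(n, 1, 0.7)
  time[event == 0] <- time[event == 0] * runif(sum(event == 0))
  list(score = score, time = time, event = event)
}

# tiny expression fixture: g genes x n samples with named dims
make_expr <- function(g, n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(g * n), nrow = g,
         dimnames = list(sprintf("g%02d", seq_len(g)),
                         sprintf("s%02d", seq_len(n))))
}
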