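test_that("KM curves follow the product-limit estimator", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # all censored: survival stays at 1
  km2 <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km2$surv == 1))
  # non-increasing within each group, and at-risk bookkeeping
  s <- make_surv(40, seed = 2)
  g <- factor(rep(c("a", "b"), 20))
  km3 <- km_curve(s$time, s$event, g)
  for (l in c("a", "b")) {
    sub <- km3[km3$group == l, ]
    expect_true(all(diff(sub$surv) <= 1e-12))
    expect_equal(sub$n_risk - sub$n_event - sub$n_censor,
                 c(sub$n_risk[-1], 0))
  }
  expect_error(km_curve(c(1, 2), c(1, 1), factor(c("a", "a"), levels = c("a", "b"))),
               "empty group")
})

test_that("log-rank statistic matches the hand oracle and survival::survdiff", {
  # 6-sample toy, all events; O/E/V accumulated by hand gives chi2 = 5.0517
  time <- 1:6; event <- rep(1, 6)
  group <- factor(rep(c("a", "b"), each = 3))
  lr <- logrank(time, event, group)
  expect_equal(lr$chi2, 3.4225 / 0.6775, tolerance = 1e-10)
  expect_equal(lr$direction, "a")  # group a dies first
  # identical groups: no signal
  lr0 <- logrank(c(1, 2, 1, 2), c(1, 1, 1, 1), factor(c("a", "a", "b", "b")))
  expect_lt(lr0$chi2, 1e-20)
  expect_equal(lr0$p, 1)
  # random instances against survdiff, with ties and censoring
  for (seed in 1:10) {
    s <- make_surv(30, seed = seed)
    s$time <- round(s$time)  + 1 # force ties
    g <- factor(rbinom(30, 1, 0.5))
    if (length(unique(g)) < 2) next
    ref <- survival::survdiff(survival::Surv(s$time, s$event) ~ g)
    mine <- logrank(s$time, s$event, g)
    expect_equal(mine$chi2, ref$chisq, tolerance = 1e-8)
  }
  expect_error(logrank(1:3, c(1, 1, 1), factor(c("a", "a", "a"),
                                               levels = c("a", "b"))),
               "empty group|two groups")
})

test_that("log-rank is symmetric under group relabelling", {
  s <- make_surv(25, seed = 4)
  g <- factor(rep(c("x", "y"), c(12, 13)))
  g_swapped <- factor(ifelse(g == "x", "y", "x"))
  a <- logrank(s$time, s$event, g)
  b <- logrank(s$time, s$event, g_swapped)
  expect_equal(a$chi2, b$chi2, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("log-rank p agrees with a permutation null on toy data", {
  s <- make_surv(20, seed = 8, beta = 0.8)
  g <- factor(rep(c("lo", "hi"), 10))
  obs <- logrank(s$time, s$event, g)
  set.seed(123)
  n_perm <- 10000
  null_chi2 <- replicate(n_perm, logrank(s$time, s$event, sample(g))$chi2)
  p_perm <- mean(null_chi2 >= obs$chi2)
  # Monte-Carlo error of the permutation estimate
  mc_se <- sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(p_perm - obs$p), max(4 * mc_se, 0.02))
})

test_that("optimal cutpoint is the exhaustive minimum over admissible splits", {
  # deaths only among the high scores: cutpoint must fall in (2, 9)
  score <- c(1, 2, 9, 10)
  time <- c(10, 12, 1, 2); event <- c(0, 0, 1, 1)
  res <- optimal_cutoff(score, time, event, min_frac = 0.25)
  expect_gt(res$cutpoint, 2); expect_lt(res$cutpoint, 9)
  expect_equal(res$direction, "high_worse")
  # against the survdiff-based exhaustive oracle on random instances
  for (seed in 1:15) {
    s <- make_surv(30, seed = seed + 100, beta = 0.4)
    mine <- optimal_cutoff(s$score, s$time, s$event, min_frac = 0.1)
    ref <- oracle_optimal_cutoff(s$score, s$time, s$event, min_frac = 0.1)
    expect_equal(mine$p, ref$p, tolerance = 1e-8)
    expect_equal(mine$chi2, ref$chi2, tolerance = 1e-8)
  }
})

test_that("optimal cutpoint respects the minimum group fraction", {
  set.seed(5)
  s <- make_surv(10, seed = 5)
  res <- optimal_cutoff(s$score, s$time, s$event, min_frac = 0.5)
  expect_equal(res$n_low, 5L)
  expect_equal(res$n_high, 5L)
  expect_error(optimal_cutoff(rep(1, 10), s$time, s$event),
               "no admissible cutpoint")
})

test_that("optimal cutpoint p never exceeds the median-split p", {
  for (seed in 1:10) {
    s <- make_surv(40, seed = seed, beta = 0.3)
    res <- optimal_cutoff(s$score, s$time, s$event, min_frac = 0.1)
    med <- logrank(s$time, s$event,
                   factor(s$score > median(s$score)))
    expect_lte(res$p, med$p + 1e-12)
  }
})

test_that("per-gene survival scan flags constant genes and matches optimal_cutoff", {
  s <- make_surv(30, seed = 9)
  m <- rbind(gene1 = s$score, gene2 = rnorm(30), const = rep(2, 30))
  colnames(m) <- sprintf("s%02d", 1:30)
  scan <- gene_survival_scan(m, s$time, s$event)
  expect_true(scan$flagged[scan$gene == "const"])
  expect_true(is.na(scan$p[scan$gene == "const"]))
  one <- optimal_cutoff(m["gene1", ], s$time, s$event)
  expect_equal(scan$p[scan$gene == "gene1"], one$p, tolerance = 1e-12)
  expect_equal(scan$cutpoint[scan$gene == "gene1"], one$cutpoint)
})

test_that("scan direction reflects planted hazard sign", {
  # strongly hazardous score: high expression must be called worse
  hits <- 0
  for (seed in 1:5) {
    s <- make_surv(120, seed = seed, beta = 1)
    m <- matrix(s$score, nrow = 1,
                dimnames = list("g", sprintf("s%03d", 1:120)))
    scan <- gene_survival_scan(m, s$time, s$event)
    hits <- hits + (scan$direction == "high_expr_worse")
  }
  expect_gte(hits, 4)
})
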