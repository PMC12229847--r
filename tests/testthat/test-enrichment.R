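test_that("two-group ranking metrics match hand formulas and flip with labels", {
  set.seed(14)
  m <- make_expr(4, 8)
  lab <- factor(rep(c("lo", "hi"), each = 4), levels = c("lo", "hi"))
  r <- rank_by_groups(m, lab, metric = "signal2noise")
  # hand signal-to-noise for one gene
  x1 <- m["g02", 1:4]; x2 <- m["g02", 5:8]
  s1 <- max(sd(x1), 0.2 * abs(mean(x1)))
  s2 <- max(sd(x2), 0.2 * abs(mean(x2)))
  expect_equal(r[["g02"]], (mean(x2) - mean(x1)) / (s1 + s2), tolerance = 1e-12)
  expect_equal(sort(unname(r), decreasing = TRUE), unname(r))
  # antisymmetry under label swap
  r2 <- rank_by_groups(m, factor(lab, levels = c("hi", "lo")))
  expect_equal(r2[names(r)], -r[names(r)], tolerance = 1e-12)
  # t metric against the oracle
  rt <- rank_by_groups(m, lab, metric = "tstat")
  expect_equal(rt[["g03"]], oracle_t(m["g03", ], lab), tolerance = 1e-12)
  expect_error(rank_by_groups(m, factor(c("a", rep("b", 7)))), "at least 3")
})

test_that("enrichment score matches the brute-force running sum", {
  ranked <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  # set = top gene, weight 0: ES = 1 at the first position
  es <- enrichment_score(ranked, "g1", weight = 0)
  expect_equal(es$ES, 1)
  expect_equal(es$running_sum, oracle_running_sum(ranked, "g1", 0))
  expect_equal(es$leading_edge, "g1")
  # set = bottom gene, weight 0: extremum -1 just before the hit
  es2 <- enrichment_score(ranked, "g5", weight = 0)
  expect_equal(es2$ES, -1)
  expect_equal(es2$running_sum, oracle_running_sum(ranked, "g5", 0))
  expect_equal(es2$leading_edge, "g5")
  expect_error(enrichment_score(ranked, "absent"), "no overlap")
  expect_error(enrichment_score(ranked, paste0("g", 1:5)), "whole")
})

test_that("running sums match the definition on random instances (N <= 10)", {
  set.seed(31)
  for (i in 1:30) {
    N <- sample(4:10, 1)
    ranked <- sort(rnorm(N), decreasing = TRUE)
    names(ranked) <- paste0("g", seq_len(N))
    set_size <- sample(seq_len(N - 1), 1)
    gs <- sample(names(ranked), set_size)
    w <- sample(c(0, 1, 2), 1)
    es <- enrichment_score(ranked, gs, weight = w)
    run <- oracle_running_sum(ranked, gs, w)
    expect_equal(es$running_sum, run, tolerance = 1e-12)
    expect_equal(es$ES, run[which.max(abs(run))], tolerance = 1e-12)
  }
})

test_that("weight-0 ES is invariant to metric rescaling and negates on reversal", {
  ranked <- setNames(c(9, 7, 3, 2, 1, 0.5), paste0("g", 1:6))
  gs <- c("g1", "g2")
  es <- enrichment_score(ranked, gs, weight = 0)$ES
  expect_equal(enrichment_score(ranked * 100, gs, weight = 0)$ES, es)
  rev_ranked <- rev(-ranked)
  expect_equal(enrichment_score(rev_ranked, gs, weight = 0)$ES, -es,
               tolerance = 1e-12)
})

test_that("ES agrees with fgsea on a shared fixture", {
  set.seed(77)
  ranked <- sort(rnorm(60), decreasing = TRUE)
  names(ranked) <- sprintf("g%02d", 1:60)
  gs <- sample(names(ranked), 12)
  mine <- enrichment_score(ranked, gs, weight = 1)$ES
  ref <- suppressWarnings(
    fgsea::calcGseaStat(ranked, which(names(ranked) %in% gs), gseaParam = 1))
  expect_equal(mine, ref, tolerance = 1e-6)
})

test_that("permutation test is deterministic and floors p for a planted set", {
  set.seed(50)
  n <- 30
  lab <- factor(rep(c("lo", "hi"), each = 15), levels = c("lo", "hi"))
  m <- make_expr(40, n, seed = 50)
  m[1:8, lab == "hi"] <- m[1:8, lab == "hi"] + 3  # strongly planted set
  planted <- rownames(m)[1:8]
  r1 <- permutation_test(m, lab, planted, n_perm = 200, seed = 42)
  r2 <- permutation_test(m, lab, planted, n_perm = 200, seed = 42)
  expect_equal(r1$ES, r2$ES)
  expect_equal(r1$nominal_p, r2$nominal_p)
  expect_lt(r1$nominal_p, 0.05)
  expect_gt(r1$NES, 1)
  # gene-set scheme: random sets of noise genes never approach the planted ES
  r3 <- permutation_test(m, lab, planted, n_perm = 200, scheme = "geneset",
                         seed = 43)
  expect_equal(r3$nominal_p, 1 / 201)  # the permutation floor
  expect_error(permutation_test(m, lab, planted, n_perm = 10), "at least 100")
})

test_that("gene-set permutation scheme gives roughly uniform p under the null", {
  set.seed(61)
  m <- make_expr(50, 20, seed = 61)
  lab <- factor(rep(c("a", "b"), each = 10))
  ps <- vapply(1:40, function(i) {
    gs <- sample(rownames(m), 10)
    permutation_test(m, lab, gs, n_perm = 100, scheme = "geneset",
                     seed = i)$nominal_p
  }, 0)
  expect_gt(mean(ps), 0.25)   # not collapsed toward 0
  expect_lt(mean(ps < 0.05), 0.25)
})

test_that("methylation-expression correlation classifies planted anticorrelation", {
  set.seed(9)
  n <- 50
  expr <- rbind(anti = rnorm(n), null = rnorm(n), short = rnorm(n))
  colnames(expr) <- sprintf("s%02d", 1:n)
  meth <- rbind(anti = -expr["anti", ], null = rnorm(n), short = rnorm(n))
  colnames(meth) <- colnames(expr)
  meth["short", 3:n] <- NA
  expect_warning(
    res <- meth_expr_correlation(meth, expr, c("anti", "null", "short")),
    "fewer than 3")
  expect_equal(res$pearson_r[res$gene == "anti"], -1)
  expect_true(res$flagged[res$gene == "anti"])
  expect_false(res$flagged[res$gene == "null"])
  expect_false("short" %in% res$gene)
  # affine invariance with positive slope
  res2 <- meth_expr_correlation(0.2 + 0.3 * meth[1:2, ], 5 + 2 * expr[1:2, ],
                                c("anti", "null"))
  expect_equal(res2$pearson_r, res$pearson_r[1:2], tolerance = 1e-12)
  # independent noise at large n stays near zero
  set.seed(10)
  big_e <- matrix(rnorm(1000), 1, dimnames = list("g", sprintf("t%04d", 1:1000)))
  big_m <- matrix(runif(1000), 1, dimnames = list("g", colnames(big_e)))
  r <- meth_expr_correlation(big_m, big_e, "g")
  expect_lt(abs(r$pearson_r), 0.1)
})
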