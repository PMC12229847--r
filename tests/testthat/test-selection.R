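test_that("ANOVA F and p match sum-of-squares and stats::oneway.test", {
  set.seed(42)
  tert <- factor(rep(c("low", "intermediate", "high"), each = 3),
                 levels = c("low", "intermediate", "high"))
  m <- matrix(rnorm(5 * 9), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:9)))
  res <- anova_trend(m, tert)
  for (i in 1:5) {
    expect_equal(res$F[i], oracle_anova_F(m[i, ], tert), tolerance = 1e-10)
    ow <- oneway.test(m[i, ] ~ tert, var.equal = TRUE)
    expect_equal(res$F[i], unname(ow$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], ow$p.value, tolerance = 1e-10)
  }
})

test_that("trend calls require strict monotonicity of tertile means", {
  tert <- factor(rep(c("low", "intermediate", "high"), each = 2),
                 levels = c("low", "intermediate", "high"))
  m <- rbind(up = c(1, 1, 2, 2, 3, 3),
             non = c(1, 1, 3, 3, 2, 2),
             down = c(3, 3, 2, 2, 1, 1),
             flat = c(1, 2, 1, 2, 1, 2))
  colnames(m) <- paste0("s", 1:6)
  res <- anova_trend(m, tert)
  expect_equal(res$trend, c("up", "none", "down", "none"))
  # near-perfect separation drives p toward 0
  expect_lt(res$p[1], 1e-6)
  expect_error(anova_trend(m, factor(rep("low", 6),
                                     levels = c("low", "intermediate", "high"))),
               "empty")
})

test_that("two-group t-tests match stats::t.test and handle degenerate input", {
  set.seed(7)
  lab <- factor(rep(c("early", "advanced"), each = 5),
                levels = c("early", "advanced"))
  m <- matrix(rnorm(40), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  res <- two_group_test(m, lab)
  for (i in 1:4) {
    tt <- t.test(m[i, lab == "advanced"], m[i, lab == "early"],
                 var.equal = TRUE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
    expect_equal(res$t[i], oracle_t(m[i, ], lab), tolerance = 1e-10)
  }
  # identical groups give t = 0, p = 1
  m2 <- rbind(g1 = rep(c(1, 2, 3, 4, 5), 2))
  colnames(m2) <- paste0("s", 1:10)
  res2 <- two_group_test(m2, lab)
  expect_equal(res2$t, 0)
  expect_equal(res2$p, 1)
  expect_equal(res2$q, res2$p)  # single gene: q == p
  expect_error(two_group_test(m, factor(c("a", rep("b", 9)))), "at least 2")
})

test_that("BH q-values match the step-up oracle", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03, 0.005)),
               oracle_bh(c(0.01, 0.04, 0.03, 0.005)))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(99)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
  }
})

test_that("three-criteria selection keeps exactly the constructed passers", {
  # 60 samples; tumor aggressiveness axis defines tertiles and stage, an
  # independent frailty w drives survival -- so a gene can pass the trend and
  # stage criteria yet fail the survival one
  n <- 60
  samples <- sprintf("s%02d", 1:n)
  axis <- rep(c(-1, 0, 1), each = 20)
  tert <- factor(rep(c("low", "intermediate", "high"), each = 20),
                 levels = c("low", "intermediate", "high"))
  stage <- factor(ifelse(axis == 1, "advanced", "early"),
                  levels = c("early", "advanced"))
  set.seed(3)
  w <- rnorm(n)
  time <- rexp(n, rate = 0.1 * exp(1.5 * w))
  clinical <- data.frame(sample_id = samples, time = time, event = rep(1, n))
  noise <- function() rnorm(n, sd = 0.3)
  m <- rbind(
    hit_up = 2 * axis + 2 * w + noise(),    # passes all three, up
    hit_dn = -2 * axis - 2 * w + noise(),   # passes all three, down
    no_trend = 2 * abs(axis) + 2 * w + noise(),  # non-monotone tertile means
    flat = noise(),                         # nothing
    no_surv = 2 * axis + noise(),           # trend+stage yes, survival no
    extra = noise())
  colnames(m) <- samples
  sel <- select_targets(m, c("hit_up", "hit_dn", "no_trend", "flat",
                             "no_surv", "not_measured"),
                        tert, stage, clinical,
                        fdr = 0.05, surv_alpha = 1e-3, min_frac = 0.2) |>
    suppressWarnings()
  expect_equal(sel$selected_up, "hit_up")
  expect_equal(sel$selected_down, "hit_dn")
  tab <- sel$table
  expect_false("not_measured" %in% tab$gene)
  expect_false("extra" %in% tab$gene)  # catalog restriction
  expect_equal(tab$trend[tab$gene == "no_trend"], "none")
  expect_false(tab$selected[tab$gene == "no_surv"])
  expect_true(all(tab$anova_q >= tab$anova_p))
  expect_error(suppressWarnings(
    select_targets(m, "absent_gene", tert, stage, clinical)), "empty")
})

test_that("flipping every expression row swaps up and down polarity", {
  co <- simulate_cohort(sim_config(n_samples = 120, n_background_genes = 60,
                                   n_weak = 10, seed = 5))
  z <- zscore_rows(co$expression)
  emt <- geneset_score(z, co$emt_genes)
  tert <- tertile_groups(emt)
  stage <- factor(co$clinical$stage, levels = c("early", "advanced"))
  sel <- select_targets(z, co$metab_genes, tert, stage, co$clinical)
  sel_neg <- select_targets(-z, co$metab_genes, tert, stage, co$clinical)
  expect_setequal(sel_neg$selected_up, sel$selected_down)
  expect_setequal(sel_neg$selected_down, sel$selected_up)
})

test_that("Tukey post hoc agrees with stats::TukeyHSD", {
  set.seed(11)
  tert <- factor(rep(c("low", "intermediate", "high"), each = 5),
                 levels = c("low", "intermediate", "high"))
  m <- matrix(rnorm(30), nrow = 2,
              dimnames = list(c("gA", "gB"), paste0("s", 1:15)))
  tk <- tukey_posthoc(m, tert)
  ref <- TukeyHSD(aov(m["gA", ] ~ tert))$tert
  expect_equal(tk$p_high_vs_low[1], ref["high-low", "p adj"], tolerance = 1e-10)
})
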