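#' Configuration for the synthetic cohort generator
#'
#' Builds the parameter list that [simulate_cohort()] consumes. The defaults
#' describe a mid-sized tumor cohort: a standard-normal latent
#' aggressiveness (EMT) axis per sample drives a 200-gene EMT program,
#' 5 planted oncogenic and 2 planted tumor-suppressor metabolic genes
#' (coupled with opposite signs), a weakly coupled co-regulated tier of
#' metabolic genes (the analog of pathway neighbours that pass differential
#' filters without being hubs), stage labels and survival hazard tied to the
#' axis, methylation anticorrelated with the suppressor genes, and an
#' interaction network in which the planted genes are hubs.
#'
#' @param n_samples Cohort size.
#' @param n_background_genes Metabolic catalog size (includes the planted
#'   and weak-tier genes).
#' @param n_emt_genes Size of the EMT hallmark program.
#' @param planted_onco,planted_ts Numbers of planted oncogenic /
#'   tumor-suppressor hub genes.
#' @param n_weak Number of weakly coupled co-regulated metabolic genes
#'   (half coupled up, half down).
#' @param emt_loading Coupling of EMT genes to the latent axis.
#' @param planted_effect Coupling of planted hub genes (sign + for
#'   oncogenic, − for suppressor).
#' @param weak_effect Coupling of the weak tier.
#' @param noise_sd Residual expression noise SD (must be > 0).
#' @param stage_threshold Latent-axis quantile above which a sample is
#'   advanced stage (before 10\% label flips).
#' @param hazard_beta Log-hazard per unit latent axis.
#' @param censor_rate Expected fraction of censored samples, in \eqn{[0,1]}.
#' @param meth_coupling Slope of suppressor-gene methylation on the latent
#'   axis (methylation rises as suppressor expression falls).
#' @param meth_noise_sd Methylation noise SD.
#' @param hub_extra_edges Extra network edges attached to each planted gene
#'   (endpoints drawn from the weak tier).
#' @param background_edge_prob Erdos–Renyi edge probability over the
#'   metabolic catalog.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_samples = 300L,
                       n_background_genes = 500L,
                       n_emt_genes = 200L,
                       planted_onco = 5L,
                       planted_ts = 2L,
                       n_weak = 40L,
                       emt_loading = 0.8,
                       planted_effect = 0.8,
                       weak_effect = 0.6,
                       noise_sd = 1,
                       stage_threshold = 0.5,
                       hazard_beta = 0.7,
                       censor_rate = 0.3,
                       meth_coupling = 0.15,
                       meth_noise_sd = 0.05,
                       hub_extra_edges = 10L,
                       background_edge_prob = 0.01,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_background_genes = as.integer(n_background_genes),
              n_emt_genes = as.integer(n_emt_genes),
              planted_onco = as.integer(planted_onco),
              planted_ts = as.integer(planted_ts),
              n_weak = as.integer(n_weak),
              emt_loading = emt_loading,
              planted_effect = planted_effect,
              weak_effect = weak_effect,
              noise_sd = noise_sd,
              stage_threshold = stage_threshold,
              hazard_beta = hazard_beta,
              censor_rate = censor_rate,
              meth_coupling = meth_coupling,
              meth_noise_sd = meth_noise_sd,
              hub_extra_edges = as.integer(hub_extra_edges),
              background_edge_prob = background_edge_prob,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_samples", "n_background_genes", "n_emt_genes",
              "planted_onco", "planted_ts")
  for (f in counts)
    if (cfg[[f]] <= 0L) stop("sim_config field '", f, "' must be positive")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$censor_rate < 0 || cfg$censor_rate > 1) stop("censor_rate must be in [0,1]")
  if (cfg$background_edge_prob < 0 || cfg$background_edge_prob > 1)
    stop("background_edge_prob must be in [0,1]")
  if (cfg$stage_threshold <= 0 || cfg$stage_threshold >= 1)
    stop("stage_threshold must be a quantile in (0,1)")
  if (cfg$planted_onco + cfg$planted_ts + cfg$n_weak > cfg$n_background_genes)
    stop("planted + weak genes exceed n_background_genes")
  invisible(cfg)
}

#' Simulate a multi-omics cohort with planted ground truth
#'
#' Generates expression, methylation, clinical annotations, and an
#' interaction network whose joint structure matches the assumptions of the
#' discovery pipeline: a latent per-sample aggressiveness axis
#' \eqn{L \sim N(0,1)} drives the EMT program, the planted hub genes
#' (positively for oncogenic, negatively for suppressor genes), the weak
#' co-regulated tier, stage labels (quantile threshold plus 10\% label
#' noise), and an exponential survival hazard \eqn{\propto
#' \exp(\beta L)} with independent censoring at the configured rate.
#' Methylation of suppressor genes rises with the axis (inducing a negative
#' methylation–expression correlation); all other genes' methylation is
#' uncorrelated noise around 0.5. The network is Erdos–Renyi over the
#' metabolic catalog plus \code{hub_extra_edges} edges from each planted
#' gene to distinct weak-tier genes.
#'
#' @param config A [sim_config()] object.
#' @return A list of class \code{"synthetic_cohort"} with elements
#'   \code{expression}, \code{methylation} (matrices), \code{clinical}
#'   (data frame), \code{edges} (canonical edge data frame), \code{truth}
#'   (named character vector in \code{onco/ts/weak_up/weak_down/emt/background}),
#'   \code{latent} (named numeric), \code{emt_genes}, \code{metab_genes},
#'   and \code{config}.
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))
  latent <- stats::rnorm(n)
  names(latent) <- sample_ids

  emt_genes <- sprintf("EMT%03d", seq_len(config$n_emt_genes))
  onco_genes <- sprintf("ONCO%d", seq_len(config$planted_onco))
  ts_genes <- sprintf("TSG%d", seq_len(config$planted_ts))
  n_wu <- config$n_weak %/% 2L
  n_wd <- config$n_weak - n_wu
  weak_up <- if (n_wu > 0L) sprintf("WUP%02d", seq_len(n_wu)) else character(0)
  weak_dn <- if (n_wd > 0L) sprintf("WDN%02d", seq_len(n_wd)) else character(0)
  n_bg <- config$n_background_genes - config$planted_onco -
    config$planted_ts - config$n_weak
  bg_genes <- if (n_bg > 0L) sprintf("BG%04d", seq_len(n_bg)) else character(0)
  metab_genes <- c(onco_genes, ts_genes, weak_up, weak_dn, bg_genes)
  all_genes <- c(emt_genes, metab_genes)

  loading <- c(rep(config$emt_loading, length(emt_genes)),
               rep(config$planted_effect, length(onco_genes)),
               rep(-config$planted_effect, length(ts_genes)),
               rep(config$weak_effect, length(weak_up)),
               rep(-config$weak_effect, length(weak_dn)),
               rep(0, length(bg_genes)))
  baseline <- stats::runif(length(all_genes), 4, 10)
  expr <- baseline + loading %o% latent +
    matrix(stats::rnorm(length(all_genes) * n, sd = config$noise_sd),
           nrow = length(all_genes))
  dimnames(expr) <- list(all_genes, sample_ids)
  attr(expr, "value_kind") <- "expression"

  # stage: advanced above the configured latent quantile, 10% label flips
  adv <- latent > stats::quantile(latent, config$stage_threshold)
  flip <- stats::runif(n) < 0.10
  adv <- xor(adv, flip)
  stage <- ifelse(adv, "advanced", "early")
  grade <- ifelse(xor(latent > stats::quantile(latent, 1 / 3),
                      stats::runif(n) < 0.10), "high", "low")

  # survival: exponential with rate rate0 * exp(beta * L), months scale
  rate0 <- log(2) / 36
  true_t <- stats::rexp(n, rate = rate0 * exp(config$hazard_beta * latent))
  censored <- stats::runif(n) < config$censor_rate
  obs_t <- ifelse(censored, true_t * stats::runif(n), true_t)
  event <- as.integer(!censored)
  progression <- as.integer(latent + stats::rnorm(n) > 0)

  clinical <- data.frame(sample_id = sample_ids,
                         stage = stage, grade = grade,
                         time = obs_t, event = event,
                         progression = progression,
                         stringsAsFactors = FALSE)

  # methylation: suppressor genes shift with the axis; everything else noise
  meth <- matrix(0.5 + stats::rnorm(length(all_genes) * n,
                                    sd = config$meth_noise_sd),
                 nrow = length(all_genes),
                 dimnames = list(all_genes, sample_ids))
  if (length(ts_genes) > 0L)
    meth[ts_genes, ] <- 0.5 + config$meth_coupling * rep(latent, each = length(ts_genes)) +
      matrix(stats::rnorm(length(ts_genes) * n, sd = config$meth_noise_sd),
             nrow = length(ts_genes))
  meth <- pmin(pmax(meth, 0), 1)
  attr(meth, "value_kind") <- "methylation"

  # network: ER over the metabolic catalog + hub edges planted -> weak tier
  m <- length(metab_genes)
  pair_i <- rep(seq_len(m - 1L), times = (m - 1L):1L)
  pair_j <- unlist(lapply(seq_len(m - 1L), function(i) (i + 1L):m))
  keep <- stats::runif(length(pair_i)) < config$background_edge_prob
  edges <- data.frame(node_a = metab_genes[pair_i[keep]],
                      node_b = metab_genes[pair_j[keep]],
                      score = round(stats::runif(sum(keep), 400, 999)),
                      stringsAsFactors = FALSE)
  planted <- c(onco_genes, ts_genes)
  weak_all <- c(weak_up, weak_dn)
  if (config$hub_extra_edges > 0L && length(weak_all) > 0L) {
    k <- min(config$hub_extra_edges, length(weak_all))
    hub_edges <- do.call(rbind, lapply(planted, function(g) {
      partners <- sample(weak_all, k)
      data.frame(node_a = g, node_b = partners,
                 score = round(stats::runif(k, 700, 999)),
                 stringsAsFactors = FALSE)
    }))
    edges <- rbind(edges, hub_edges)
  }
  edges <- suppressWarnings(canonicalize_edges(edges))

  truth <- c(stats::setNames(rep("emt", length(emt_genes)), emt_genes),
             stats::setNames(rep("onco", length(onco_genes)), onco_genes),
             stats::setNames(rep("ts", length(ts_genes)), ts_genes),
             stats::setNames(rep("weak_up", length(weak_up)), weak_up),
             stats::setNames(rep("weak_down", length(weak_dn)), weak_dn),
             stats::setNames(rep("background", length(bg_genes)), bg_genes))

  structure(list(expression = expr, methylation = meth, clinical = clinical,
                 edges = edges, truth = truth, latent = latent,
                 emt_genes = emt_genes, metab_genes = metab_genes,
                 config = config),
            class = "synthetic_cohort")
}

#' Realized properties of the planted genes
#'
#' Reports, for every planted (and weak-tier) gene, its realized Pearson
#' correlation with the latent axis, the mean expression difference between
#' advanced- and early-stage samples, and its degree in the generated
#' network — a direct check that the generator planted what it was asked to.
#'
#' @param cohort A [simulate_cohort()] result.
#' @return A data frame with columns \code{gene}, \code{truth},
#'   \code{latent_cor}, \code{stage_diff}, \code{degree}.
#' @export
truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  genes <- names(cohort$truth)[cohort$truth %in%
                                 c("onco", "ts", "weak_up", "weak_down")]
  adv <- cohort$clinical$stage == "advanced"
  deg_tab <- table(c(cohort$edges$node_a, cohort$edges$node_b))
  data.frame(
    gene = genes,
    truth = unname(cohort$truth[genes]),
    latent_cor = vapply(genes, function(g)
      stats::cor(cohort$expression[g, ], cohort$latent), 0),
    stage_diff = vapply(genes, function(g)
      mean(cohort$expression[g, adv]) - mean(cohort$expression[g, !adv]), 0),
    degree = vapply(genes, function(g)
      if (g %in% names(deg_tab)) as.integer(deg_tab[[g]]) else 0L, 0L),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a synthetic cohort to disk in the pipeline's file dialects
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             methylation = file.path(dir, "methylation.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             edges = file.path(dir, "edges.tsv"),
             truth = file.path(dir, "truth.tsv"),
             emt = file.path(dir, "genesets.gmt"))
  write_expression(cohort$expression, paths[["expression"]])
  write_expression(cohort$methylation, paths[["methylation"]])
  write_table(cohort$clinical, paths[["clinical"]])
  write_table(cohort$edges, paths[["edges"]])
  write_table(data.frame(gene = names(cohort$truth),
                         truth = unname(cohort$truth),
                         stringsAsFactors = FALSE), paths[["truth"]])
  writeLines(c(paste(c("HALLMARK_EMT", "synthetic EMT program",
                       cohort$emt_genes), collapse = "\t"),
               paste(c("METABOLIC_CATALOG", "synthetic metabolic catalog",
                       cohort$metab_genes), collapse = "\t")),
             paths[["emt"]])
  invisible(paths)
}
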