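# Synthetic cohorts with the statistical structure the pipeline assumes:
# log-normal expression, a minority of prognostic genes acting on the hazard
# through their standardized log-expression, proportional-hazards
# (exponential) survival, independent uniform right censoring calibrated to
# a target fraction, and stage labels correlated with the hazard.
#
# Hazards act on STANDARDIZED log-expression, so a gene's raw magnitude
# carries no prognostic information by construction. That separation is what
# lets the simulator plant very highly expressed uninformative
# ("mitochondrial-like") genes next to lowly expressed informative ones —
# the failure mode the wavelet preprocessing is meant to counter.

#' Simulation configuration
#'
#' @param n_samples Cohort size (default 300).
#' @param n_genes Gene count (default 2000).
#' @param n_prognostic Number of planted prognostic genes (default 20).
#' @param beta True log-hazard per SD of log-expression for planted genes;
#'   scalar or length `n_prognostic` (default 1).
#' @param log_mean,log_sd Baseline log-expression mean and SD (defaults 2, 1;
#'   expression = exp(Normal), FPKM-like).
#' @param n_high_nuisance Very highly expressed uninformative genes
#'   (log-mean shifted by `high_shift`; default 10 genes, +5).
#' @param n_low_informative How many of the planted genes are lowly expressed
#'   (log-mean shifted by `low_shift`; default 5 genes, -2).
#' @param high_shift,low_shift Log-mean shifts described above.
#' @param censor_frac Target right-censoring fraction (default 0.3).
#' @param baseline_hazard Exponential baseline hazard per day (default
#'   `log(2)/1095`: median survival of three years at zero linear predictor).
#' @param stage_noise Probability that a sample's stage group is flipped
#'   relative to its hazard (default 0.1).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 300L, n_genes = 2000L, n_prognostic = 20L,
                       beta = 1, log_mean = 2, log_sd = 1,
                       n_high_nuisance = 10L, n_low_informative = 5L,
                       high_shift = 5, low_shift = -2,
                       censor_frac = 0.3, baseline_hazard = log(2) / 1095,
                       stage_noise = 0.1, seed = 1L) {
  stopifnot(n_prognostic + n_high_nuisance <= n_genes,
            n_low_informative <= n_prognostic,
            censor_frac >= 0, censor_frac < 1,
            stage_noise >= 0, stage_noise <= 1,
            baseline_hazard > 0, log_sd > 0)
  beta <- rep_len(beta, n_prognostic)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an expression + clinical cohort with known ground truth
#'
#' @param cfg A [sim_config()].
#' @return A list with `expression` (genes x samples matrix), `clinical`
#'   (data.frame: `sample_id`, `os_days`, `vital_status`, `tumor_stage`),
#'   `truth` (planted gene ids, their true betas, and the per-sample linear
#'   predictor) and `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  p <- cfg$n_genes; n <- cfg$n_samples; k <- cfg$n_prognostic
  gene_ids <- sprintf("g%05d", seq_len(p))
  sample_ids <- sprintf("s%04d", seq_len(n))

  roles <- sample.int(p, k + cfg$n_high_nuisance)
  planted <- roles[seq_len(k)]
  nuisance <- roles[k + seq_len(cfg$n_high_nuisance)]
  low_informative <- planted[seq_len(cfg$n_low_informative)]

  mu <- rep(cfg$log_mean, p)
  mu[nuisance] <- mu[nuisance] + cfg$high_shift
  mu[low_informative] <- mu[low_informative] + cfg$low_shift
  logx <- matrix(stats::rnorm(p * n, mean = mu, sd = cfg$log_sd), p, n,
                 dimnames = list(gene_ids, sample_ids))
  expr <- exp(logx)

  z <- logx[planted, , drop = FALSE]
  z <- (z - rowMeans(z)) / apply(z, 1, stats::sd)
  lp <- drop(crossprod(z, cfg$beta))  # per-sample log relative hazard

  t_event <- stats::rexp(n, rate = cfg$baseline_hazard * exp(lp))
  if (cfg$censor_frac > 0) {
    frac <- function(cmax) mean(pmin(t_event / cmax, 1)) - cfg$censor_frac
    cmax <- stats::uniroot(frac, c(1e-6, max(t_event) * 1e6))$root
    cens <- stats::runif(n, 0, cmax)
  } else {
    cens <- rep(Inf, n)
  }
  obs <- pmin(t_event, cens)
  dead <- t_event <= cens

  high_hazard <- lp > stats::median(lp)
  flip <- stats::runif(n) < cfg$stage_noise
  high_stage <- xor(high_hazard, flip)
  stage <- ifelse(high_stage,
                  sample(c("Stage III", "Stage IIIA", "Stage IV"), n, TRUE),
                  sample(c("Stage I", "Stage II", "Stage IIA"), n, TRUE))

  clinical <- data.frame(
    sample_id = sample_ids,
    os_days = pmax(1, round(obs)),
    vital_status = ifelse(dead, "dead", "alive"),
    tumor_stage = stage,
    stringsAsFactors = FALSE
  )
  truth <- list(planted = gene_ids[planted],
                beta = stats::setNames(cfg$beta, gene_ids[planted]),
                nuisance = gene_ids[nuisance],
                low_informative = gene_ids[low_informative],
                linear_predictor = stats::setNames(lp, sample_ids))
  list(expression = expr, clinical = clinical, truth = truth, config = cfg)
}

#' Achievable AUC ceiling for a simulation configuration
#'
#' Monte-Carlo estimate of the AUC reached by the Bayes-optimal score — the
#' true linear predictor — against the 3-year survival endpoint under the
#' given configuration. The pipeline's validation AUC should approach but
#' not exceed this ceiling.
#'
#' @param cfg A [sim_config()].
#' @param reps Number of Monte-Carlo cohorts (default 20).
#' @param horizon_days Endpoint horizon (default 1095).
#' @param seed Seed for the replicate cohorts.
#' @return Estimated upper-bound AUC.
#' @export
expected_auc_bound <- function(cfg = sim_config(), reps = 20L,
                               horizon_days = 1095, seed = cfg$seed) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, reps)
  vals <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    c2 <- cfg; c2$seed <- rep_seeds[r]
    sim <- simulate_cohort(c2)
    coh <- tryCatch(suppressMessages(
      derive_survival_labels(sim$clinical, horizon_days)),
      error = function(e) NULL)
    if (is.null(coh)) next
    vals[r] <- auc(coh$label, sim$truth$linear_predictor[coh$sample_id])
  }
  mean(vals, na.rm = TRUE)
}
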