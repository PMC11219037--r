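#' One-step-ahead posterior predictions
#'
#' For each posterior draw the latent values are rolled forward on the
#' observed choice-outcome history, so every trial's predicted
#' contingent-choice probability conditions only on earlier trials.
#' Reported per trial: the posterior-mean probability of the contingent
#' option and of the observed choice, and a 95% highest-density
#' interval over the posterior.  Predictive accuracy per wave is the
#' proportion of trials whose posterior-mean probability of the
#' observed choice exceeds 0.5, with exact ties counting one half.
#'
#' @param fit An `rlwaves_fit` fitted on `data`.
#' @param data The fitted `choice_data` frame (defaults to the data
#'   stored in the fit).
#' @param n_draws Number of posterior draws used (thinned evenly across
#'   chains; default 400).
#' @param hdi_prob HDI mass (default 0.95).
#' @return A list: `trials` data frame (`mean_p` contingent,
#'   `p_observed`, `hdi_low`, `hdi_high`, `observed_choice`),
#'   `accuracy` per wave, `overall` accuracy.
#' @export
one_step_ahead <- function(fit, data = NULL, n_draws = 400,
                           hdi_prob = 0.95) {
  stopifnot(inherits(fit, "rlwaves_fit"))
  if (is.null(data)) data <- fit$data
  data <- as_choice_data(data)
  if (!setequal(unique(data$subject_id), fit$subjects))
    stop("dataset subjects do not match the fitted draws")
  th <- fit$theta
  n_iter <- dim(th)[1]; n_chain <- dim(th)[2]
  take <- unique(round(seq(1, n_iter, length.out =
                             max(1, ceiling(n_draws / n_chain)))))
  pn <- dimnames(th)[[5]]
  enc <- encode_dataset(data)
  pmat <- matrix(NA_real_, length(take) * n_chain, nrow(data))
  row <- 0
  for (ch in seq_len(n_chain)) for (it in take) {
    row <- row + 1
    pars <- data.frame(subject_id = rep(dimnames(th)[[3]], 2),
                       wave = rep(1:2, each = dim(th)[3]),
                       stringsAsFactors = FALSE)
    for (p in seq_along(pn))
      pars[[pn[p]]] <- c(th[it, ch, , 1, p], th[it, ch, , 2, p])
    pmat[row, ] <- latent_p_contingent(data, pars, fit$spec)
  }
  mean_p <- colMeans(pmat)
  hdis <- apply(pmat, 2, hdi, prob = hdi_prob)
  obs_cont <- data$choice == "contingent"
  p_obs <- ifelse(data$choice == "none", NA,
                  ifelse(obs_cont, mean_p, 1 - mean_p))
  trials <- data.frame(
    subject_id = data$subject_id, wave = data$wave,
    trial_index = data$trial_index, condition = data$condition,
    observed_choice = data$choice, mean_p = mean_p,
    p_observed = p_obs, hdi_low = hdis[1, ], hdi_high = hdis[2, ],
    stringsAsFactors = FALSE)
  valid <- !is.na(p_obs)
  # ties at one half (to numerical precision) score one half
  acc_of <- function(p)
    mean(ifelse(abs(p - 0.5) < 1e-6, 0.5, ifelse(p > 0.5, 1, 0)))
  accuracy <- tapply(p_obs[valid], data$wave[valid], acc_of)
  list(trials = trials, accuracy = accuracy,
       overall = acc_of(p_obs[valid]))
}

#' Highest-density interval of a sample
#'
#' @param x Numeric draws.
#' @param prob Interval mass.
#' @return `c(lower, upper)` of the shortest interval containing
#'   `prob` of the draws.
#' @export
hdi <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1, ceiling(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - m)
  widths <- x[starts + m] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

#' Parameter recovery study
#'
#' Simulates a cohort with known individual parameters, refits it
#' hierarchically, and correlates the generating values with the
#' posterior-mean individual estimates, per free parameter (wave-pooled
#' and per wave), together with bias and RMSE.
#'
#' @param config A [cohort_config()] describing the generating
#'   population (poor-learner fraction and non-responses are disabled
#'   here: recovery concerns the value-based model).
#' @param mcmc An [mcmc_config()].
#' @param seed Optional integer master seed.
#' @param task_args Passed to [generate_task()].
#' @return An `rlwaves_recovery` list: `per_parameter` data frame
#'   (parameter, r, bias, rmse), `fit`, `truth`, `estimate`.
#' @export
parameter_recovery <- function(config, mcmc = mcmc_config(), seed = NULL,
                               task_args = list()) {
  config$poor_learner_fraction <- 0
  config$nonresponse_rate <- c(0, 0)
  cohort <- generate_cohort(config, seed = seed, task_args = task_args)
  spec <- model_spec(config$model_id)
  for (pn in spec$params$name)
    if (sd(cohort$params$value[cohort$params$parameter == pn]) < 1e-12)
      stop("generating values for ", pn, " have zero variance; ",
           "recovery correlation undefined")
  fit <- fit_hierarchical(cohort$data, spec,
                          mcmc = within_seed(mcmc, stage_seed(seed, "refit")))
  est <- individual_means(fit)
  truth <- cohort$params
  per <- lapply(spec$params$name, function(pn) {
    tr <- truth[truth$parameter == pn, ]
    key <- paste(tr$subject_id, tr$wave)
    ekey <- paste(est$subject_id, est$wave)
    idx <- match(key, ekey)
    ok <- !is.na(idx)
    tv <- tr$value[ok]; ev <- est[[pn]][idx[ok]]
    if (sd(tv) < 1e-12)
      stop("generating values for ", pn, " have zero variance; ",
           "recovery correlation undefined")
    data.frame(parameter = pn, r = cor(tv, ev),
               r_w1 = cor(tv[tr$wave[ok] == 1], ev[tr$wave[ok] == 1]),
               r_w2 = cor(tv[tr$wave[ok] == 2], ev[tr$wave[ok] == 2]),
               bias = mean(ev - tv), rmse = sqrt(mean((ev - tv)^2)),
               stringsAsFactors = FALSE)
  })
  structure(list(per_parameter = do.call(rbind, per), fit = fit,
                 truth = truth, estimate = est),
            class = "rlwaves_recovery")
}

within_seed <- function(mcmc, seed) {
  if (!is.null(seed)) mcmc$seed <- seed
  mcmc
}

#' Model recovery study
#'
#' Simulates `n_datasets` cohorts from a generating model, fits every
#' candidate model to each, and selects models at two levels: group
#' level by total PSIS-LOO elpd, individual level by each subject's sum
#' of pointwise elpd.  Returns confusion counts for both levels.
#'
#' @param generating_config A [cohort_config()] for the generating
#'   model (its `model_id` must be among the candidates).
#' @param candidates Character vector of candidate model ids.
#' @param n_datasets Number of simulated cohorts (>= 1).
#' @param mcmc An [mcmc_config()].
#' @param seed Optional integer master seed.
#' @param task_args Passed to [generate_task()].
#' @return An `rlwaves_model_recovery` list: `group` (data frame of the
#'   selected model per dataset), `group_rate` (proportion of datasets
#'   selecting the generator), `individual` (table of per-subject best
#'   models pooled over datasets), `individual_rate`.
#' @export
model_recovery <- function(generating_config, candidates, n_datasets,
                           mcmc = mcmc_config(), seed = NULL,
                           task_args = list()) {
  if (n_datasets < 1) stop("n_datasets must be >= 1")
  gen_id <- generating_config$model_id
  if (!gen_id %in% candidates)
    stop("generating model must be among the candidates")
  group <- character(n_datasets)
  indiv <- list()
  for (d in seq_len(n_datasets)) {
    cohort <- generate_cohort(generating_config,
                              seed = stage_seed(seed, paste0("dataset", d)),
                              task_args = task_args)
    data <- drop_nonresponses(cohort$data)
    elpds <- numeric(length(candidates))
    subj_elpd <- NULL
    for (m in seq_along(candidates)) {
      sp <- model_spec(candidates[m])
      fit <- fit_hierarchical(data, sp,
        mcmc = within_seed(mcmc, stage_seed(seed, paste0("fit", d, candidates[m]))))
      loo <- elpd_loo(fit)
      elpds[m] <- loo$elpd
      per_sub <- tapply(loo$pointwise$elpd, data$subject_id, sum)
      if (is.null(subj_elpd))
        subj_elpd <- matrix(NA_real_, length(per_sub), length(candidates),
                            dimnames = list(names(per_sub), candidates))
      subj_elpd[, m] <- per_sub
    }
    group[d] <- candidates[which.max(elpds)]
    indiv[[d]] <- candidates[apply(subj_elpd, 1, which.max)]
  }
  indiv_all <- unlist(indiv)
  structure(list(
    group = data.frame(dataset = seq_len(n_datasets), selected = group,
                       stringsAsFactors = FALSE),
    group_rate = mean(group == gen_id),
    individual = table(factor(indiv_all, levels = candidates)),
    individual_rate = mean(indiv_all == gen_id),
    generating = gen_id, candidates = candidates),
    class = "rlwaves_model_recovery")
}
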