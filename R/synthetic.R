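#' Generate a task design
#'
#' Builds the probabilistic feedback task: `n_cues` cues (two per
#' feedback-timing condition), each shown `trials_per_cue` times across
#' `n_blocks` blocks in a pseudo-randomized interleaved order with no cue
#' repeated more than `max_run` times in a row.  Outcomes follow an exact
#' schedule: per cue, exactly `round(contingency * trials_per_cue)` of
#' the presentations reward the contingent option (28 of 32 at the
#' default 87.5% contingency) and the complement rewards the other
#' option, so the learning environment is identical for every agent
#' regardless of its choices.
#'
#' @param version Counterbalancing version 1-4; rotates which cues carry
#'   immediate vs delayed feedback.
#' @param n_cues,trials_per_cue,n_blocks,contingency Task geometry;
#'   defaults give the standard 128-trial, 4-block design.
#' @param max_run Maximum run length of one cue in the trial order.
#' @param seed Optional integer seed.
#' @return An `rl_task` object: `$trials` (trial_index, block, cue_id,
#'   condition), `$schedule` (cue x presentation 0/1 matrix for the
#'   contingent option), `$cues`, `$condition_map`.
#' @export
generate_task <- function(version = 1, n_cues = 4, trials_per_cue = 32,
                          n_blocks = 4, contingency = 0.875,
                          max_run = 3, seed = NULL) {
  if (!version %in% 1:4) stop("version must be 1, 2, 3 or 4")
  per_block <- trials_per_cue / n_blocks
  if (per_block != round(per_block))
    stop("trials_per_cue must be divisible by n_blocks")
  if (n_cues %% 2 != 0) stop("n_cues must be even (two per condition)")
  maybe_set_seed(seed)
  cues <- paste0("cue", seq_len(n_cues))
  # counterbalancing: rotate the immediate/delayed assignment by version
  half <- n_cues / 2
  imm <- ((seq_len(half) - 1 + (version - 1)) %% n_cues) + 1
  condition_map <- setNames(rep("delayed", n_cues), cues)
  condition_map[imm] <- "immediate"

  order_block <- function() {
    repeat {
      o <- sample(rep(seq_len(n_cues), per_block))
      r <- rle(o)
      if (max(r$lengths) <= max_run) return(o)
    }
  }
  cue_seq <- unlist(lapply(seq_len(n_blocks), function(b) order_block()))
  n_reward <- round(contingency * trials_per_cue)
  schedule <- t(vapply(seq_len(n_cues), function(k)
    sample(rep(c(1L, 0L), c(n_reward, trials_per_cue - n_reward))),
    integer(trials_per_cue)))
  trials <- data.frame(
    trial_index = seq_along(cue_seq),
    block = rep(seq_len(n_blocks), each = n_cues * per_block),
    cue_id = cues[cue_seq],
    condition = unname(condition_map[cue_seq]),
    stringsAsFactors = FALSE)
  structure(list(trials = trials, schedule = schedule, cues = cues,
                 condition_map = condition_map, version = version,
                 contingency = contingency, n_reward = n_reward,
                 trials_per_cue = trials_per_cue, n_blocks = n_blocks),
            class = "rl_task")
}

#' Configure a synthetic two-wave cohort
#'
#' Holds the population-level settings for [generate_cohort()]: sample
#' size and attrition, the group mean/SD of every free parameter on the
#' unconstrained (probit) scale per wave, the cross-wave correlation of
#' subject-level effects, the fraction of heuristic-strategy "poor
#' learner" subjects, and per-wave non-response rates.
#'
#' The default moments target the descriptive statistics of a two-wave
#' developmental sample fitted with the condition-split inverse
#' temperature model (`vbm3`): learning rate means 0.02 (wave 1) and
#' 0.05 (wave 2) with SDs 0.02/0.04, inverse temperatures around
#' 14.6-14.8 rising to 16.2-16.5 with SDs near 2-2.4.  The unconstrained
#' moments are solved numerically so that the induced bounded means and
#' SDs match these targets exactly.
#'
#' @param n_subjects Wave-1 sample size.
#' @param retention Proportion retained at wave 2.
#' @param model_id Generating value-based model.
#' @param moments Named list, one entry per free parameter, each a list
#'   with `mu` and `sigma` length-2 vectors (wave 1, wave 2) on the
#'   unconstrained scale.
#' @param cross_wave_cor Correlation of a subject's unconstrained effect
#'   across waves, in (-1, 1).
#' @param poor_learner_fraction Fraction of subjects generated from the
#'   `wsls` heuristic instead of the value-based model.
#' @param poor_moments Unconstrained moments of the poor learners'
#'   `tau_strategy` (low values keep them near chance).
#' @param nonresponse_rate Length-2 per-wave probability that a trial is
#'   a non-response.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 140,
                          retention = 0.9,
                          model_id = "vbm3",
                          moments = NULL,
                          cross_wave_cor = 0.5,
                          poor_learner_fraction = 13 / 140,
                          poor_moments = list(mu = c(-2.1, -2.1),
                                              sigma = c(0.4, 0.4)),
                          nonresponse_rate = c(0.0241, 0.0097)) {
  if (retention < 0 || retention > 1) stop("retention must be in [0, 1]")
  if (poor_learner_fraction < 0 || poor_learner_fraction > 1)
    stop("poor_learner_fraction must be in [0, 1]")
  if (any(nonresponse_rate < 0 | nonresponse_rate > 1))
    stop("nonresponse_rate must be in [0, 1]")
  if (abs(cross_wave_cor) >= 1)
    stop("cross_wave_cor must lie strictly in (-1, 1)")
  spec <- model_spec(model_id)
  if (spec$family == "heuristic")
    stop("the cohort's main generating model must be value-based")
  if (is.null(moments)) moments <- default_moments(spec)
  miss <- setdiff(spec$params$name, names(moments))
  if (length(miss))
    stop("moments missing for parameter(s): ", paste(miss, collapse = ", "))
  for (m in moments)
    if (any(m$sigma < 0)) stop("moment SDs must be non-negative")
  structure(list(n_subjects = n_subjects, retention = retention,
                 model_id = model_id, moments = moments,
                 cross_wave_cor = cross_wave_cor,
                 poor_learner_fraction = poor_learner_fraction,
                 poor_moments = poor_moments,
                 nonresponse_rate = nonresponse_rate),
            class = "cohort_config")
}

# Mean and SD of theta = lb + (ub-lb)*Phi(mu + sig*Z), Z ~ N(0,1).
# First moment is closed-form; the second uses quadrature.
bounded_moments <- function(mu, sig, lb, ub) {
  m1 <- pnorm(mu / sqrt(1 + sig^2))
  m2 <- stats::integrate(function(z) pnorm(mu + sig * z)^2 * dnorm(z),
                         -8, 8, rel.tol = 1e-10)$value
  c(mean = lb + (ub - lb) * m1,
    sd = (ub - lb) * sqrt(max(0, m2 - m1^2)))
}

# Solve for the unconstrained (mu, sigma) whose induced bounded mean/SD
# hit the targets exactly (the probit link is convex near the bounds, so
# a delta-method inversion would bias small means noticeably).
solve_moments <- function(target_mean, target_sd, lb, ub) {
  key <- paste(target_mean, target_sd, lb, ub, sep = "|")
  hit <- .moment_cache[[key]]
  if (!is.null(hit)) return(hit)
  z0 <- qnorm((target_mean - lb) / (ub - lb))
  s0 <- target_sd / ((ub - lb) * dnorm(z0))
  obj <- function(par) {
    ms <- bounded_moments(par[1], exp(par[2]), lb, ub)
    (ms[1] - target_mean)^2 / target_sd^2 + (ms[2] - target_sd)^2 / target_sd^2
  }
  o <- stats::optim(c(z0, log(max(s0, 1e-3))), obj, method = "Nelder-Mead",
                    control = list(maxit = 1000, reltol = 1e-13))
  out <- c(mu = o$par[1], sigma = exp(o$par[2]))
  .moment_cache[[key]] <- out
  out
}

.moment_cache <- new.env(parent = emptyenv())

# Unconstrained-scale group moments matching the reference descriptive
# table, obtained by exact numerical inversion of the bounded probit link.
default_moments <- function(spec) {
  targets <- list(
    alpha     = list(mean = c(0.02, 0.05), sd = c(0.02, 0.04)),
    alpha_imm = list(mean = c(0.02, 0.05), sd = c(0.02, 0.04)),
    alpha_del = list(mean = c(0.02, 0.05), sd = c(0.02, 0.04)),
    tau       = list(mean = c(14.7, 16.35), sd = c(2.2, 2.3)),
    tau_imm   = list(mean = c(14.6, 16.2), sd = c(2.04, 2.37)),
    tau_del   = list(mean = c(14.8, 16.5), sd = c(2.37, 2.21)),
    rho       = list(mean = c(14.7, 16.35), sd = c(2.2, 2.3)),
    rho_imm   = list(mean = c(14.6, 16.2), sd = c(2.04, 2.37)),
    rho_del   = list(mean = c(14.8, 16.5), sd = c(2.37, 2.21)))
  out <- list()
  for (j in seq_len(nrow(spec$params))) {
    nm <- spec$params$name[j]
    lb <- spec$params$lower[j]; ub <- spec$params$upper[j]
    tg <- targets[[nm]]
    sol <- vapply(1:2, function(w)
      solve_moments(tg$mean[w], tg$sd[w], lb, ub), numeric(2))
    out[[nm]] <- list(mu = sol["mu", ], sigma = sol["sigma", ])
  }
  out
}

#' Draw ground-truth individual parameters
#'
#' Samples each subject's unconstrained effect for every free parameter
#' from a bivariate normal across waves (correlation
#' `config$cross_wave_cor`) with the configured per-wave means and SDs,
#' then maps through the bounded probit transform.
#'
#' @param config A [cohort_config()].
#' @param n Number of subjects (defaults to `config$n_subjects`).
#' @param seed Optional integer seed.
#' @return Long data frame: `subject_id`, `wave`, `model_id`,
#'   `parameter`, `value` (bounded), `z` (unconstrained).
#' @export
draw_true_params <- function(config, n = config$n_subjects, seed = NULL) {
  maybe_set_seed(seed)
  spec <- model_spec(config$model_id)
  r <- config$cross_wave_cor
  out <- list()
  for (j in seq_len(nrow(spec$params))) {
    nm <- spec$params$name[j]
    m <- config$moments[[nm]]
    z1 <- rnorm(n)
    z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
    x1 <- m$mu[1] + m$sigma[1] * z1
    x2 <- m$mu[2] + m$sigma[2] * z2
    lb <- spec$params$lower[j]; ub <- spec$params$upper[j]
    out[[nm]] <- data.frame(
      subject_id = rep(sprintf("s%03d", seq_len(n)), 2),
      wave = rep(c(1L, 2L), each = n),
      model_id = config$model_id, parameter = nm,
      value = bounded_transform(c(x1, x2), lb, ub),
      z = c(x1, x2), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Generate a synthetic two-wave cohort
#'
#' Simulates a full longitudinal dataset with the structure the
#' hierarchical analysis assumes: per-subject parameters drawn across
#' waves with the configured correlation, a deterministic count of
#' wsls-strategy poor learners with low strategy weight, fresh cues (and
#' a fresh task draw) at wave 2, missing-completely-at-random wave-2
#' attrition, and uniformly injected non-responses.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer master seed; task, parameter, and choice
#'   randomness derive named sub-seeds from it.
#' @param task_args Extra arguments passed to [generate_task()] (e.g.
#'   `trials_per_cue` to scale the task down).
#' @return An `rl_cohort` list: `$data` (a `choice_data` frame),
#'   `$params` (true-parameter table including poor learners'
#'   `tau_strategy`), `$poor_learners` (subject ids), `$tasks`.
#' @export
generate_cohort <- function(config, seed = NULL, task_args = list()) {
  stopifnot(inherits(config, "cohort_config"))
  maybe_set_seed(stage_seed(seed, "cohort"))
  n <- config$n_subjects
  spec <- model_spec(config$model_id)
  wsls <- model_spec("wsls")

  n_poor <- round(config$poor_learner_fraction * n)
  ids <- sprintf("s%03d", seq_len(n))
  poor_ids <- if (n_poor > 0) sample(ids, n_poor) else character(0)

  truth <- draw_true_params(config, n = n)
  # poor learners: replace their value-model rows with a wsls strategy weight
  if (n_poor > 0) {
    r <- config$cross_wave_cor
    pm <- config$poor_moments
    z1 <- rnorm(n_poor)
    z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n_poor)
    poor <- data.frame(
      subject_id = rep(poor_ids, 2), wave = rep(c(1L, 2L), each = n_poor),
      model_id = "wsls", parameter = "tau_strategy",
      value = bounded_transform(c(pm$mu[1] + pm$sigma[1] * z1,
                                  pm$mu[2] + pm$sigma[2] * z2), 0, 20),
      z = c(pm$mu[1] + pm$sigma[1] * z1, pm$mu[2] + pm$sigma[2] * z2),
      stringsAsFactors = FALSE)
    truth <- rbind(truth[!truth$subject_id %in% poor_ids, ], poor)
  }

  # one task draw per counterbalancing version per wave
  tasks <- lapply(1:2, function(w)
    lapply(1:4, function(v)
      do.call(generate_task,
              c(list(version = v, seed = stage_seed(seed, paste0("task", w, v))),
                task_args))))

  retained <- sample(ids, round(config$retention * n))
  maybe_set_seed(stage_seed(seed, "choices"))
  rows <- list()
  for (i in seq_len(n)) {
    id <- ids[i]
    waves <- if (id %in% retained || config$retention == 1) 1:2 else 1L
    for (w in waves) {
      task <- tasks[[w]][[(i - 1) %% 4 + 1]]
      if (id %in% poor_ids) {
        sp <- wsls
        pv <- truth[truth$subject_id == id & truth$wave == w, ]
        pars <- setNames(pv$value, pv$parameter)
      } else {
        sp <- spec
        pv <- truth[truth$subject_id == id & truth$wave == w, ]
        pars <- setNames(pv$value, pv$parameter)
      }
      nr <- runif(nrow(task$trials)) < config$nonresponse_rate[w]
      rows[[length(rows) + 1]] <-
        simulate_agent(task, pars, sp, nonresponse = nr,
                       subject_id = id, wave = w)
    }
  }
  data <- as_choice_data(do.call(rbind, rows))
  structure(list(data = data, params = truth, poor_learners = poor_ids,
                 retained = retained, config = config, tasks = tasks),
            class = "rl_cohort")
}

#' Write the true-parameter table of a cohort
#'
#' @param cohort An `rl_cohort`.
#' @param path Output CSV path.
#' @export
write_true_params <- function(cohort, path) {
  write.csv(cohort$params[, c("subject_id", "wave", "model_id",
                              "parameter", "value")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
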