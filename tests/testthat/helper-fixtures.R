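# Shared builders for desk-scale fixtures; everything is generated in
# code at test time.

quick_mcmc <- function(seed = 1, chains = 2, iter = 600, thin = 3)
  mcmc_config(n_chains = chains, n_iter = iter, thin_loglik = thin,
              seed = seed)

quick_config <- function(n = 12, model = "vbm1", ...)
  cohort_config(n_subjects = n, retention = 1, poor_learner_fraction = 0,
                nonresponse_rate = c(0, 0), model_id = model, ...)

# hand-built single-subject dataset from explicit trial tuples
manual_data <- function(choices, rewards, cue = "cueA",
                        condition = "immediate", subject = "s1", wave = 1L) {
  n <- length(choices)
  as_choice_data(data.frame(
    subject_id = subject, wave = wave, trial_index = seq_len(n),
    block = 1L, cue_id = cue, condition = condition,
    choice = choices, reward = rewards, stringsAsFactors = FALSE))
}

# empty dataset with the right columns
empty_data <- function()
  as_choice_data(data.frame(
    subject_id = character(0), wave = integer(0), trial_index = integer(0),
    block = integer(0), cue_id = character(0), condition = character(0),
    choice = character(0), reward = integer(0), stringsAsFactors = FALSE))

# pure-R reference agent: replays an observed history and returns the
# latent contingent-choice probability before each trial (independent
# oracle for the compiled trial loop)
reference_probs <- function(data, pars, model_id) {
  spec <- model_spec(model_id)
  fam <- spec$family
  p_out <- numeric(nrow(data))
  for (key in unique(paste(data$subject_id, data$wave))) {
    rows <- which(paste(data$subject_id, data$wave) == key)
    init <- if (fam == "heuristic") 0.5 else 0
    v1 <- v0 <- NULL
    for (i in rows) {
      cue <- data$cue_id[i]
      if (is.null(v1)) { v1 <- list(); v0 <- list() }
      if (is.null(v1[[cue]])) { v1[[cue]] <- init; v0[[cue]] <- init }
      cond <- data$condition[i]
      tau <- if (fam == "heuristic") pars$tau_strategy
             else if (fam == "outcome_sensitivity") 1
             else if (spec$split_tau) pars[[paste0("tau_", substr(cond, 1, 3))]]
             else pars$tau
      p <- plogis(tau * (v1[[cue]] - v0[[cue]]))
      p_out[i] <- p
      if (data$choice[i] == "none") next
      ch <- data$choice[i] == "contingent"
      r <- data$reward[i]
      if (fam == "heuristic") {
        if (r == 1) { v1[[cue]] <- if (ch) 1 else 0 }
        else if (model_id == "wsls") { v1[[cue]] <- if (ch) 0 else 1 }
        else { v1[[cue]] <- 0.5 }
        v0[[cue]] <- if (r == 0 && model_id == "ws") 0.5 else 1 - v1[[cue]]
      } else {
        a <- if (spec$split_alpha) pars[[paste0("alpha_", substr(cond, 1, 3))]]
             else pars$alpha
        rho <- if (fam == "outcome_sensitivity") {
          if (spec$split_rho) pars[[paste0("rho_", substr(cond, 1, 3))]]
          else pars$rho
        } else 1
        target <- if (fam == "inverse_temperature") 2 * r - 1 else rho * r
        if (ch) v1[[cue]] <- v1[[cue]] + a * (target - v1[[cue]])
        else    v0[[cue]] <- v0[[cue]] + a * (target - v0[[cue]])
      }
    }
  }
  p_out
}

# minimal rlwaves_fit with a point-mass posterior at fixed parameters
point_fit <- function(data, values, model_id, n_iter = 4, n_chain = 2) {
  spec <- model_spec(model_id)
  subs <- sort(unique(data$subject_id))
  pn <- spec$params$name
  th <- array(NA_real_, c(n_iter, n_chain, length(subs), 2, length(pn)),
              dimnames = list(NULL, NULL, subs, c("w1", "w2"), pn))
  for (p in seq_along(pn)) th[, , , , p] <- values[[pn[p]]]
  structure(list(spec = spec, subjects = subs, data = data, theta = th,
                 mcmc = mcmc_config(n_chains = n_chain, n_iter = n_iter * 2),
                 converged = TRUE),
            class = "rlwaves_fit")
}
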