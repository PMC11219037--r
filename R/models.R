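#' Model specifications
#'
#' Builds the specification for one of the ten candidate learning models:
#' two heuristic strategy models (`ws`, `wsls`) whose single parameter
#' scales the use of a win-stay (and lose-shift) weight, and eight
#' Rescorla-Wagner value-based variants.  The value-based variants cross
#' a single vs condition-split learning rate with either an inverse
#' temperature (`vbm1`-`vbm4`, outcome sensitivity fixed at 1) or an
#' outcome sensitivity (`vbm5`-`vbm8`, inverse temperature fixed at 1),
#' each again single or split by feedback-timing condition:
#' vbm1 = (1a,1t), vbm2 = (2a,1t), vbm3 = (1a,2t), vbm4 = (2a,2t),
#' vbm5 = (1a,1r), vbm6 = (2a,1r), vbm7 = (1a,2r), vbm8 = (2a,2r).
#'
#' The two value-based families learn different outcome codings, which
#' keeps them distinct models rather than reparameterizations of one
#' another: the inverse-temperature family updates values toward a
#' signed valence (+1 reward, -1 punishment), while the
#' outcome-sensitivity family updates toward the scaled reward event
#' `rho * r` with `r` in {0, 1}, so punishments drive its values
#' toward zero.
#'
#' @param model_id One of `"ws"`, `"wsls"`, `"vbm1"`..`"vbm8"`.
#' @return An object of class `rl_model_spec` listing the free
#'   parameters, their bounds, and the mapping onto the simulator slots.
#' @export
model_spec <- function(model_id) {
  model_id <- match.arg(model_id, c("ws", "wsls", paste0("vbm", 1:8)))
  heur <- model_id %in% c("ws", "wsls")
  slots <- c("alpha_imm", "alpha_del", "tau_imm", "tau_del",
             "rho_imm", "rho_del")
  if (heur) {
    family <- "heuristic"
    split_alpha <- split_tau <- split_rho <- FALSE
    params <- data.frame(name = "tau_strategy", lower = 0, upper = 20,
                         stringsAsFactors = FALSE)
    map <- matrix(0L, 6, 1, dimnames = list(slots, "tau_strategy"))
    map[c("tau_imm", "tau_del"), 1] <- 1L
    base <- c(0, 0, 0, 0, 1, 1)
    code <- if (model_id == "ws") 0L else 1L
    label <- paste0("1τ", model_id)
  } else {
    k <- as.integer(sub("vbm", "", model_id))
    family <- if (k <= 4) "inverse_temperature" else "outcome_sensitivity"
    split_alpha <- k %in% c(2, 4, 6, 8)
    split_tau <- family == "inverse_temperature" && k %in% c(3, 4)
    split_rho <- family == "outcome_sensitivity" && k %in% c(7, 8)
    pn <- if (split_alpha) c("alpha_imm", "alpha_del") else "alpha"
    sec <- if (family == "inverse_temperature") "tau" else "rho"
    pn <- c(pn, if (k %in% c(3, 4, 7, 8)) paste0(sec, c("_imm", "_del")) else sec)
    params <- data.frame(name = pn,
                         lower = 0,
                         upper = ifelse(grepl("^alpha", pn), 1, 20),
                         stringsAsFactors = FALSE)
    map <- matrix(0L, 6, length(pn), dimnames = list(slots, pn))
    for (j in seq_along(pn)) {
      stem <- sub("_(imm|del)$", "", pn[j])
      tgt <- if (grepl("_imm$", pn[j])) paste0(stem, "_imm")
             else if (grepl("_del$", pn[j])) paste0(stem, "_del")
             else paste0(stem, c("_imm", "_del"))
      map[tgt, j] <- 1L
    }
    # fixed slots: tau or rho pinned at 1 depending on family
    base <- c(0, 0, 1, 1, 1, 1)
    code <- if (family == "inverse_temperature") 2L else 3L
    label <- paste0(if (split_alpha) "2α, " else "1α, ",
                    if (k %in% c(3, 4, 7, 8)) "2" else "1",
                    if (family == "inverse_temperature") "τ" else "ρ")
  }
  structure(list(model_id = model_id, family = family,
                 split_alpha = split_alpha, split_tau = split_tau,
                 split_rho = split_rho, params = params, par_map = map,
                 par_base = base, model_code = code, label = label),
            class = "rl_model_spec")
}

#' @export
print.rl_model_spec <- function(x, ...) {
  cat("<rl_model_spec>", x$model_id, sprintf("(%s)", x$label), "\n")
  cat("  family:", x$family, "\n")
  cat("  free parameters:",
      paste(sprintf("%s in (%g, %g)", x$params$name, x$params$lower,
                    x$params$upper), collapse = ", "), "\n")
  invisible(x)
}

# Expand a named list/vector of free parameter values for one agent into
# the 6-slot row consumed by the C++ kernels.
param_row <- function(spec, params) {
  params <- unlist(params)
  miss <- setdiff(spec$params$name, names(params))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  bad <- params[spec$params$name] <= spec$params$lower |
         params[spec$params$name] >= spec$params$upper
  if (any(bad))
    stop("parameter(s) outside their open bounds: ",
         paste(spec$params$name[bad], collapse = ", "))
  row <- spec$par_base
  for (j in seq_len(ncol(spec$par_map)))
    row[spec$par_map[, j] == 1L] <- params[[colnames(spec$par_map)[j]]]
  row
}

#' Delta-rule value update
#'
#' Updates the value of the chosen option from the received outcome via
#' the reward prediction error: `v + alpha * (rho * outcome - v)`.  The
#' unchosen option's value is untouched by definition.  Iterating the
#' update under a constant outcome contracts the value to
#' `rho * outcome` at rate `(1 - alpha)`.
#'
#' The generative value-based models in this package feed the update a
#' signed outcome valence, +1 for a reward event and -1 for a
#' punishment, the coding under which the task's simulated optimum
#' reproduces; the update itself accepts any real outcome value.
#'
#' @param v Current value of the chosen option.
#' @param outcome Received outcome value (e.g. +1 reward, -1 or 0
#'   punishment).
#' @param alpha Learning rate in (0, 1).
#' @param rho Outcome sensitivity (> 0); scales the received outcome.
#' @return The updated value.
#' @examples
#' update_value(0.5, 1, alpha = 0.1)        # 0.55
#' update_value(0.2, 0, alpha = 0.5)        # decay toward 0
#' update_value(0, 1, alpha = 0.5, rho = 10) # 5
#' @export
update_value <- function(v, outcome, alpha, rho = 1) {
  if (any(alpha <= 0 | alpha >= 1))
    stop("alpha must lie strictly in (0, 1)")
  if (any(rho <= 0)) stop("rho must be positive")
  if (any(!is.finite(outcome))) stop("outcome must be finite")
  v + alpha * (rho * outcome - v)
}

#' Softmax choice probability for a two-option pair
#'
#' Probability of selecting the first option under the pairwise softmax
#' `exp(tau * v1) / (exp(tau * v1) + exp(tau * v2))`, computed through
#' the overflow-safe difference form.
#'
#' @param v_chosen,v_other Option values.
#' @param tau Inverse temperature (>= 0; 0 gives random choice).
#' @return Probability in (0, 1).
#' @examples
#' choice_prob(1, 0, tau = log(3))  # 0.75
#' @export
choice_prob <- function(v_chosen, v_other, tau) {
  if (any(!is.finite(v_chosen) | !is.finite(v_other) | !is.finite(tau)))
    stop("non-finite input to choice_prob")
  if (any(tau < 0)) stop("tau must be non-negative")
  p <- stats::plogis(tau * (v_chosen - v_other))
  pmin(pmax(p, 1e-12), 1 - 1e-12)  # keep strictly inside (0, 1)
}

#' Heuristic strategy weight update
#'
#' Updates the (chosen, unchosen) win-stay weights of one cue after an
#' outcome.  A reward sets the chosen option's weight to 1 and the other
#' to 0 (both strategies).  After a punishment, `wsls` flips the weights
#' (maximal lose-shift) while `ws` resets to the indifferent (0.5, 0.5)
#' pair, since the win-stay strategy carries no prescription for losses.
#'
#' @param weights Numeric pair `c(w_chosen, w_unchosen)`.
#' @param reward 0 or 1.
#' @param strategy `"ws"` or `"wsls"`.
#' @return The updated weight pair (ordered chosen, unchosen).
#' @export
update_heuristic <- function(weights, reward, strategy = c("ws", "wsls")) {
  strategy <- match.arg(strategy)
  if (!reward %in% c(0, 1)) stop("reward must be 0 or 1")
  if (length(weights) != 2 || any(weights < 0 | weights > 1))
    stop("weights must be a pair in [0, 1]")
  if (reward == 1) c(1, 0)
  else if (strategy == "wsls") c(0, 1)
  else c(0.5, 0.5)
}

#' Simulate a single agent on a task
#'
#' Plays one agent through a task design under a model specification,
#' sampling choices from its latent probabilities and outcomes from the
#' task's exact reward schedule.  Values and weights evolve on the
#' agent's own sampled history.
#'
#' @param task A task design from [generate_task()].
#' @param params Named list/vector of the model's free parameters.
#' @param spec An [model_spec()] object (default `vbm1`).
#' @param seed Optional integer seed.
#' @param nonresponse Optional logical vector marking forced
#'   non-response trials (no choice, no update).
#' @param subject_id,wave Labels stamped on the returned records.
#' @return A `choice_data` data frame with a `p_contingent` column
#'   holding each trial's pre-choice latent probability of the
#'   contingent option.
#' @export
simulate_agent <- function(task, params, spec = model_spec("vbm1"),
                           seed = NULL, nonresponse = NULL,
                           subject_id = "sim", wave = 1L) {
  stopifnot(inherits(task, "rl_task"))
  maybe_set_seed(seed)
  tr <- task$trials
  if (is.null(nonresponse)) nonresponse <- rep(FALSE, nrow(tr))
  out <- cpp_simulate_block(
    cue = match(tr$cue_id, task$cues) - 1L,
    cond = as.integer(tr$condition == "delayed"),
    sched = task$schedule,
    nonresp = as.integer(nonresponse),
    par6 = param_row(spec, params),
    model_code = spec$model_code,
    n_cues = length(task$cues))
  as_choice_data(data.frame(
    subject_id = subject_id, wave = as.integer(wave),
    trial_index = tr$trial_index, block = tr$block,
    cue_id = tr$cue_id, condition = tr$condition,
    choice = ifelse(out$choice < 0, "none",
                    ifelse(out$choice == 1, "contingent", "noncontingent")),
    reward = out$reward,
    p_contingent = out$p_contingent,
    stringsAsFactors = FALSE))
}

#' Per-trial log-likelihood of observed choices
#'
#' Conditions each model's latent values/weights on the observed
#' choice-outcome history and returns the log-probability of every
#' valid-response trial's observed choice, in the canonical row order of
#' the dataset.  The sum over trials is the joint log-likelihood; the
#' per-trial decomposition is what leave-one-out cross-validation
#' consumes.
#'
#' @param data A `choice_data` data frame cleaned of non-responses (rows
#'   with `choice == "none"` are an error here; see
#'   [drop_nonresponses()]).
#' @param params Data frame of per-subject-per-wave parameter values
#'   with columns `subject_id`, `wave`, and one column per free
#'   parameter of `spec`.
#' @param spec An [model_spec()] object.
#' @return Numeric vector of per-trial log-likelihoods.
#' @export
pointwise_loglik <- function(data, params, spec) {
  enc <- encode_dataset(data)
  if (any(enc$choice < 0))
    stop("dataset contains non-response trials; drop them first")
  pars <- matrix(0, length(enc$blk_start), 6)
  for (b in seq_along(enc$blk_start)) {
    key <- params$subject_id == enc$block_key$subject_id[b] &
           params$wave == enc$block_key$wave[b]
    if (sum(key) != 1)
      stop("params must contain exactly one row per subject-wave; missing ",
           enc$block_key$subject_id[b], " wave ", enc$block_key$wave[b])
    pars[b, ] <- param_row(spec, params[key, spec$params$name, drop = FALSE])
  }
  out <- cpp_pointwise_loglik(enc$blk_start, enc$blk_len, enc$cue, enc$cond,
                              enc$choice, enc$reward, pars,
                              spec$model_code, enc$n_cues)
  out$loglik
}

# Latent contingent-choice probabilities rolled forward on the observed
# history at fixed parameters; same alignment as pointwise_loglik but
# tolerates (and skips updates at) non-response rows.
latent_p_contingent <- function(data, params, spec) {
  enc <- encode_dataset(data)
  pars <- matrix(0, length(enc$blk_start), 6)
  for (b in seq_along(enc$blk_start)) {
    key <- params$subject_id == enc$block_key$subject_id[b] &
           params$wave == enc$block_key$wave[b]
    if (sum(key) != 1)
      stop("params must contain exactly one row per subject-wave")
    pars[b, ] <- param_row(spec, params[key, spec$params$name, drop = FALSE])
  }
  out <- cpp_pointwise_loglik(enc$blk_start, enc$blk_len, enc$cue, enc$cond,
                              enc$choice, enc$reward, pars,
                              spec$model_code, enc$n_cues)
  out$p_contingent
}
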