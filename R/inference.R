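#' Bounded probit transform
#'
#' Maps an unconstrained real to the open interval (lower, upper) via
#' the standard normal CDF: `lower + (upper - lower) * pnorm(z)`.  This
#' is the link through which all group- and subject-level effects reach
#' their bounded parameter scales; `bounded_inverse()` is its exact
#' inverse.
#'
#' @param z Unconstrained value(s).
#' @param x Bounded value(s).
#' @param lower,upper Interval bounds, `lower < upper`.
#' @return Transformed value(s).
#' @examples
#' bounded_transform(0, 0, 20)  # 10
#' @export
bounded_transform <- function(z, lower, upper) {
  if (any(lower >= upper)) stop("lower must be < upper")
  lower + (upper - lower) * pnorm(z)
}

#' @rdname bounded_transform
#' @export
bounded_inverse <- function(x, lower, upper) {
  if (any(lower >= upper)) stop("lower must be < upper")
  qnorm((x - lower) / (upper - lower))
}

#' Hierarchical prior specification
#'
#' Group-level priors on the unconstrained scale: locations
#' Normal(0, `loc_sd`), scales half-Normal(0, `scale_sd`), and an
#' LKJ(`lkj_eta`) prior on each free parameter's 2x2 cross-wave
#' correlation of subject-level effects.
#'
#' @param loc_sd,scale_sd,lkj_eta Prior hyperparameters.
#' @return A `hier_spec` list.
#' @export
hier_spec <- function(loc_sd = 0.5, scale_sd = 0.5, lkj_eta = 2) {
  if (lkj_eta != 2)
    stop("only the LKJ(2) shape is implemented")
  structure(list(loc_sd = loc_sd, scale_sd = scale_sd, lkj_eta = lkj_eta),
            class = "hier_spec")
}

#' MCMC configuration
#'
#' @param n_chains Number of chains (default 4).
#' @param n_iter Iterations per chain including warmup (default 3000).
#' @param warmup_frac Fraction of each chain used as adaptation/warmup
#'   (default 0.5, i.e. 4 x 1500 = 6000 saved draws at the defaults).
#' @param thin_loglik Keep every `thin_loglik`-th saved draw's pointwise
#'   log-likelihood matrix (memory control for LOO; 1 keeps all).
#' @param seed Optional integer seed; chains derive sub-seeds.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 4, n_iter = 3000, warmup_frac = 0.5,
                        thin_loglik = 1, seed = NULL) {
  if (n_chains < 1 || n_iter < 4) stop("invalid MCMC configuration")
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 warmup_frac = warmup_frac,
                 thin_loglik = as.integer(thin_loglik),
                 seed = seed),
            class = "mcmc_config")
}

#' Fit a model hierarchically over both waves
#'
#' Estimates a learning model for all subjects jointly: subject-level
#' parameters are probit-linked unconstrained effects drawn, per free
#' parameter, from a bivariate normal over waves whose correlation
#' carries the longitudinal structure (non-centered parameterisation
#' with a Cholesky factor, LKJ(2) prior).  Group locations and scales
#' are estimated simultaneously with the subject effects by an adaptive
#' Metropolis-within-Gibbs sampler that alternates subject-local
#' likelihood updates, data-informed group updates, and
#' likelihood-invariant centered-coordinate moves for the group
#' location/scale (an interweaving scheme that keeps mixing fast when
#' the data are informative).  Subjects present at only one wave
#' contribute likelihood there; their other-wave effects remain latent
#' draws from the hierarchical prior.
#'
#' @param data A `choice_data` frame cleaned of non-responses.
#' @param spec An [model_spec()].
#' @param hspec A [hier_spec()].
#' @param mcmc An [mcmc_config()].
#' @return An `rlwaves_fit` object: posterior draw arrays for group
#'   locations/scales/correlations and bounded individual parameters,
#'   the pointwise log-likelihood draws, and convergence diagnostics.
#'   If any monitored Rhat is >= 1.1 the fit is flagged
#'   (`fit$converged == FALSE`) but still returned.
#' @export
fit_hierarchical <- function(data, spec, hspec = hier_spec(),
                             mcmc = mcmc_config()) {
  enc <- encode_dataset(data)
  if (any(enc$choice < 0))
    stop("dataset contains non-response trials; use drop_nonresponses()")
  P <- nrow(spec$params)
  n_warm <- floor(mcmc$n_iter * mcmc$warmup_frac)
  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    maybe_set_seed(stage_seed(mcmc$seed, paste0("chain", ch)))
    chains[[ch]] <- cpp_fit_hier(
      enc$blk_start, enc$blk_len, enc$sub_of_blk, enc$wave_of_blk,
      enc$cue, enc$cond, enc$choice, enc$reward,
      enc$n_sub, enc$n_cues, spec$model_code,
      spec$params$lower, spec$params$upper, spec$par_map, spec$par_base,
      hspec$loc_sd, hspec$scale_sd,
      mcmc$n_iter, n_warm, mcmc$thin_loglik,
      mu0 = rnorm(P * 2, 0, 0.1), eta0 = rnorm(P * 2, -1.2, 0.1),
      y0 = rnorm(P, 0, 0.1), z0 = rnorm(max(1, enc$n_sub) * 2 * P))
  }
  n_save <- mcmc$n_iter - n_warm
  pn <- spec$params$name
  gq <- c(paste0("mu_", rep(pn, each = 2), "_w", 1:2),
          paste0("sigma_", rep(pn, each = 2), "_w", 1:2),
          paste0("r_", pn))
  # group draws: [iteration, chain, quantity]
  group <- array(NA_real_, c(n_save, mcmc$n_chains, length(gq)),
                 dimnames = list(NULL, NULL, gq))
  for (ch in seq_len(mcmc$n_chains)) {
    group[, ch, seq_len(2 * P)] <- chains[[ch]]$mu
    group[, ch, 2 * P + seq_len(2 * P)] <- chains[[ch]]$sigma
    group[, ch, 4 * P + seq_len(P)] <- chains[[ch]]$r
  }
  theta <- NULL
  if (enc$n_sub > 0) {
    theta <- array(NA_real_, c(n_save, mcmc$n_chains, enc$n_sub, 2, P),
                   dimnames = list(NULL, NULL, enc$subjects, c("w1", "w2"), pn))
    for (ch in seq_len(mcmc$n_chains))
      theta[, ch, , , ] <- array(chains[[ch]]$theta,
                                 c(n_save, enc$n_sub, 2, P))
  }
  log_lik <- do.call(rbind, lapply(chains, function(x)
    x$log_lik[seq_len(x$n_kept_ll), , drop = FALSE]))
  diag <- convergence_table(group, theta)
  fit <- structure(list(
    spec = spec, hspec = hspec, mcmc = mcmc,
    subjects = enc$subjects, block_key = enc$block_key,
    data = enc$data, group = group, theta = theta, log_lik = log_lik,
    total_ll = sapply(chains, function(x) x$total_ll),
    final_total_ll = chains[[mcmc$n_chains]]$final_total_ll,
    diagnostics = diag,
    converged = !any(diag$rhat >= 1.1, na.rm = TRUE)),
    class = "rlwaves_fit")
  fit
}

# theta arrays are (iter, chain, sub, wave, param); group (iter, chain, q)
convergence_table <- function(group, theta) {
  qs <- dimnames(group)[[3]]
  rows <- lapply(seq_along(qs), function(j) {
    x <- group[, , j, drop = FALSE]
    dim(x) <- dim(group)[1:2]
    data.frame(quantity = qs[j], rhat = rhat_split(x), ess = ess_basic(x),
               stringsAsFactors = FALSE)
  })
  if (!is.null(theta)) {
    dn <- dimnames(theta)
    for (i in seq_along(dn[[3]])) for (w in 1:2) for (p in seq_along(dn[[5]])) {
      x <- theta[, , i, w, p, drop = FALSE]
      dim(x) <- dim(theta)[1:2]
      rows[[length(rows) + 1]] <- data.frame(
        quantity = paste0("theta_", dn[[3]][i], "_w", w, "_", dn[[5]][p]),
        rhat = rhat_split(x), ess = ess_basic(x), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$divergent <- NA_integer_  # no divergence notion for an RW sampler
  out$flagged <- !is.na(out$rhat) & out$rhat >= 1.1
  out
}

#' Convergence report
#'
#' Split-Rhat and a crude effective sample size for every monitored
#' quantity of a fit; quantities with Rhat >= 1.1 are flagged.
#'
#' @param fit An `rlwaves_fit`.
#' @return Data frame `quantity`, `rhat`, `ess`, `divergent`, `flagged`.
#' @export
convergence_report <- function(fit) {
  stopifnot(inherits(fit, "rlwaves_fit"))
  if (fit$mcmc$n_chains < 2)
    stop("convergence assessment requires at least 2 chains")
  fit$diagnostics
}

#' Split-Rhat potential scale reduction
#'
#' @param x Matrix of draws, iterations x chains.
#' @return The split-chain Rhat (NA if degenerate).
#' @export
rhat_split <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x) %/% 2
  if (n < 2) return(NA_real_)
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  cm <- colMeans(halves)
  cv <- apply(halves, 2, var)
  W <- mean(cv)
  B <- n * var(cm)
  if (!is.finite(W) || W <= 1e-300) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size via Geyer's initial positive sequence on the
# chain-averaged autocorrelation (split chains).
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(NA_real_)
  W <- mean(apply(x, 2, var))
  if (!is.finite(W) || W <= 1e-300) return(NA_real_)
  rho_sum <- 0
  max_lag <- min(n - 2, 200)
  prev <- Inf
  t <- 1
  while (t < max_lag) {
    rho_t <- mean(sapply(seq_len(m), function(j) {
      xc <- x[, j] - mean(x[, j])
      sum(xc[1:(n - t)] * xc[(t + 1):n]) / (n * W)
    }))
    rho_t1 <- mean(sapply(seq_len(m), function(j) {
      xc <- x[, j] - mean(x[, j])
      if (t + 1 >= n) return(0)
      sum(xc[1:(n - t - 1)] * xc[(t + 2):n]) / (n * W)
    }))
    pair <- rho_t + rho_t1
    if (pair < 0) break
    pair <- min(pair, prev)  # initial monotone sequence
    prev <- pair
    rho_sum <- rho_sum + pair
    t <- t + 2
  }
  max(1, n * m / (1 + 2 * rho_sum))
}

#' Posterior summary of a fit
#'
#' @param object An `rlwaves_fit`.
#' @param ... Unused.
#' @return Data frame with mean, sd, 5% and 95% quantiles and Rhat for
#'   every monitored group-level quantity, plus the bounded group means
#'   (`gm_*`, the probit-transformed locations on each parameter's
#'   natural scale).
#' @export
summary.rlwaves_fit <- function(object, ...) {
  g <- object$group
  qs <- dimnames(g)[[3]]
  P <- nrow(object$spec$params)
  rows <- lapply(seq_along(qs), function(j) {
    x <- as.vector(g[, , j])
    data.frame(quantity = qs[j], mean = mean(x), sd = sd(x),
               q5 = quantile(x, 0.05), q95 = quantile(x, 0.95),
               rhat = object$diagnostics$rhat[j], stringsAsFactors = FALSE)
  })
  for (p in seq_len(P)) for (w in 1:2) {
    mu <- as.vector(g[, , (p - 1) * 2 + w])
    gm <- bounded_transform(mu, object$spec$params$lower[p],
                            object$spec$params$upper[p])
    rows[[length(rows) + 1]] <- data.frame(
      quantity = paste0("gm_", object$spec$params$name[p], "_w", w),
      mean = mean(gm), sd = sd(gm), q5 = quantile(gm, 0.05),
      q95 = quantile(gm, 0.95), rhat = NA_real_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior means of individual bounded parameters
#'
#' @param fit An `rlwaves_fit`.
#' @return Data frame `subject_id`, `wave`, one column per free
#'   parameter (posterior means on the bounded scale).
#' @export
individual_means <- function(fit) {
  stopifnot(inherits(fit, "rlwaves_fit"))
  th <- fit$theta
  pm <- apply(th, c(3, 4, 5), mean)  # sub x wave x param
  pn <- dimnames(th)[[5]]
  out <- expand.grid(subject_id = dimnames(th)[[3]], wave = 1:2,
                     stringsAsFactors = FALSE)
  for (p in seq_along(pn)) out[[pn[p]]] <- c(pm[, 1, p], pm[, 2, p])
  out <- out[order(out$subject_id, out$wave), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a flat CSV of posterior summaries
#'
#' @param fit An `rlwaves_fit`.
#' @param path Output path.
#' @export
write_posterior_summary <- function(fit, path) {
  s <- summary(fit)
  s$rhat <- round(s$rhat, 4)
  write.csv(s, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
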