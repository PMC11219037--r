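test_that("bounded probit link is exact and invertible", {
  expect_equal(bounded_transform(0, 0, 1), 0.5)
  expect_equal(bounded_transform(0, 0, 20), 10)
  grid <- seq(-5, 5, length.out = 101)
  expect_equal(bounded_inverse(bounded_transform(grid, 0, 20), 0, 20),
               grid, tolerance = 1e-10)
  expect_true(all(diff(bounded_transform(grid, 0, 1)) > 0))
  expect_error(bounded_transform(0, 2, 1), "lower")
})

test_that("split-Rhat separates mixed from unmixed chains", {
  set.seed(2)
  white <- matrix(rnorm(4000), 1000, 4)
  expect_lt(rhat_split(white), 1.01)
  stuck <- cbind(rnorm(500, 0), rnorm(500, 5))
  expect_gt(rhat_split(stuck), 2)
})

test_that("convergence report covers all monitored quantities", {
  coh <- generate_cohort(quick_config(n = 4), seed = 2)
  fit <- fit_hierarchical(coh$data, model_spec("vbm1"),
                          mcmc = quick_mcmc(seed = 3, iter = 300))
  rep <- convergence_report(fit)
  # 5 group rows per free parameter + one per subject-wave-parameter
  expect_equal(nrow(rep), 5 * 2 + 4 * 2 * 2)
  expect_true(all(c("rhat", "ess", "divergent", "flagged") %in% names(rep)))
  fit1 <- fit
  fit1$mcmc$n_chains <- 1
  expect_error(convergence_report(fit1), "chains")
})

test_that("sampler-internal likelihood equals the pointwise decomposition", {
  coh <- generate_cohort(quick_config(n = 4), seed = 7)
  fit <- fit_hierarchical(coh$data, model_spec("vbm1"),
                          mcmc = quick_mcmc(seed = 5, iter = 300, chains = 2))
  th <- fit$theta
  last <- dim(th)[1]
  pars <- data.frame(subject_id = rep(dimnames(th)[[3]], 2),
                     wave = rep(1:2, each = dim(th)[3]))
  for (p in seq_along(dimnames(th)[[5]]))
    pars[[dimnames(th)[[5]][p]]] <- c(th[last, 2, , 1, p], th[last, 2, , 2, p])
  expect_equal(sum(pointwise_loglik(coh$data, pars, fit$spec)),
               fit$final_total_ll, tolerance = 1e-8)
  # stored pointwise log-lik rows exponentiate to probabilities
  expect_true(all(fit$log_lik <= 0))
  expect_equal(ncol(fit$log_lik), nrow(coh$data))
})

# group moments giving clearly identified individual parameters
identified_moments <- list(
  alpha = list(mu = c(-1.2, -1.0), sigma = c(0.4, 0.4)),
  tau = list(mu = c(-0.6, -0.4), sigma = c(0.5, 0.5)))

test_that("individual estimates shrink toward the group with less data", {
  coh <- generate_cohort(quick_config(n = 10, moments = identified_moments),
                         seed = 21, task_args = list(trials_per_cue = 32))
  spec <- model_spec("vbm1")
  full <- fit_hierarchical(coh$data, spec, mcmc = quick_mcmc(seed = 2, iter = 500))
  # keep only the first 3 presentations of every cue
  sub <- coh$data[ave(seq_len(nrow(coh$data)),
                      paste(coh$data$subject_id, coh$data$wave,
                            coh$data$cue_id),
                      FUN = seq_along) <= 3, ]
  small <- fit_hierarchical(as_choice_data(sub), spec,
                            mcmc = quick_mcmc(seed = 2, iter = 500))
  sf <- individual_means(full); ss <- individual_means(small)
  # compare dispersion on the unconstrained scale so the bounded link's
  # curvature does not confound the comparison
  spread <- function(x) mean(abs(x - mean(x)))
  expect_lt(spread(qnorm(ss$alpha)), spread(qnorm(sf$alpha)))
  expect_lt(spread(qnorm(ss$tau / 20)), spread(qnorm(sf$tau / 20)) + 0.05)
})

test_that("fits on informative cohorts converge at the default run length", {
  coh <- generate_cohort(quick_config(n = 30, moments = identified_moments),
                         seed = 42)
  fit <- fit_hierarchical(coh$data, model_spec("vbm1"),
                          mcmc = mcmc_config(n_chains = 4, n_iter = 3000,
                                             thin_loglik = 30, seed = 7))
  expect_true(fit$converged)
  expect_true(all(fit$diagnostics$rhat < 1.1, na.rm = TRUE))
  # posterior group means on the bounded scale sit near the generating ones
  s <- summary(fit)
  tr <- coh$params
  for (pn in c("alpha", "tau")) for (w in 1:2) {
    gm <- s$mean[s$quantity == paste0("gm_", pn, "_w", w)]
    true_mean <- mean(tr$value[tr$parameter == pn & tr$wave == w])
    expect_equal(gm, true_mean, tolerance = 0.25)
  }
})
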