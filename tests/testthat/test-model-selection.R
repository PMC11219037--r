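test_that("degenerate point-mass posteriors give exact elpd", {
  n <- 40
  ll <- matrix(log(0.5), nrow = 8, ncol = n)
  loo <- elpd_loo(ll)
  expect_equal(loo$elpd, n * log(0.5))
  expect_equal(loo$se, 0)
  expect_equal(loo$n_bad_k, 0)
  expect_error(elpd_loo(matrix(c(0, -Inf), 2, 1)), "non-finite")
})

test_that("PSIS-LOO matches exact leave-one-out on a conjugate toy", {
  # Bernoulli observations with a Beta(1,1) prior: the true leave-one-out
  # predictive density is available in closed form
  y <- c(1L, 1L, 0L, 1L, 0L)
  n <- length(y)
  set.seed(31)
  S <- 8000
  theta <- rbeta(S, 1 + sum(y), 1 + n - sum(y))
  ll <- sapply(y, function(yi) dbinom(yi, 1, theta, log = TRUE))
  exact <- sapply(seq_len(n), function(i) {
    a <- 1 + sum(y[-i]); b <- 1 + (n - 1) - sum(y[-i])
    log(if (y[i] == 1) a / (a + b) else b / (a + b))
  })
  loo <- elpd_loo(ll)
  expect_lt(max(abs(loo$pointwise$elpd - exact)), 0.05)
  expect_lt(abs(loo$elpd - sum(exact)), 0.05)
})

test_that("LOO never beats the in-sample predictive density", {
  coh <- generate_cohort(quick_config(n = 4), seed = 4)
  fit <- fit_hierarchical(coh$data, model_spec("vbm1"),
                          mcmc = quick_mcmc(seed = 6, iter = 400))
  loo <- elpd_loo(fit)
  expect_lte(loo$elpd, loo$lpd)
  expect_equal(loo$n, nrow(coh$data))
})

test_that("pseudo-BMA+ weights behave at the symmetry and dominance poles", {
  set.seed(8)
  base <- rnorm(1000, -0.6, 0.3)
  w_same <- pseudo_bma_plus(list(a = base, b = base), n_boot = 5000, seed = 1)
  expect_equal(unname(w_same), c(0.5, 0.5), tolerance = 0.01)
  w_dom <- pseudo_bma_plus(list(good = base, bad = base - 1),
                           n_boot = 5000, seed = 2)
  expect_gt(w_dom["good"], 0.999)
  expect_equal(pseudo_bma_plus(list(only = base)), c(only = 1))
  expect_equal(sum(w_dom), 1, tolerance = 1e-9)
  # invariance to a constant shift of every model's pointwise values
  w_shift <- pseudo_bma_plus(list(good = base + 3, bad = base + 2),
                             n_boot = 5000, seed = 2)
  expect_equal(unname(w_dom), unname(w_shift), tolerance = 0.01)
  expect_error(pseudo_bma_plus(list(a = base, b = base[-1])), "misaligned")
})

test_that("bootstrap size barely moves the weights on fixed inputs", {
  set.seed(9)
  pw <- list(m1 = rnorm(800, -0.5, 0.4), m2 = rnorm(800, -0.52, 0.4))
  w_small <- pseudo_bma_plus(pw, n_boot = 10000, seed = 3)
  w_big <- pseudo_bma_plus(pw, n_boot = 100000, seed = 4)
  expect_lt(max(abs(w_small - w_big)), 0.01)
})

test_that("comparison tables satisfy their structural invariants", {
  mk_loo <- function(v) { l <- elpd_loo(matrix(rep(v, each = 4), 4)); l }
  set.seed(10)
  base <- log(runif(300, 0.3, 0.9))
  loos <- list(better = mk_loo(base), self = mk_loo(base),
               worse = mk_loo(base - 0.1))
  cmp <- compare_models(loos, n_boot = 3000, seed = 5)
  expect_equal(cmp$delta_elpd[1], 0)
  expect_equal(sum(cmp$weight), 1, tolerance = 1e-6)
  expect_true(all(diff(cmp$elpd_sum) <= 0))
  # identical models split the weight and differ by zero
  two <- compare_models(loos[c("better", "self")], n_boot = 4000, seed = 6)
  expect_equal(two$delta_elpd, c(0, 0))
  expect_equal(two$weight, c(0.5, 0.5), tolerance = 0.02)
  short <- elpd_loo(matrix(rep(base[-1], each = 4), 4))
  expect_error(compare_models(list(a = loos$better, b = short)), "trial counts")
})

test_that("a wsls-generated cohort is won by the wsls model", {
  cfg <- cohort_config(n_subjects = 8, retention = 1,
                       poor_learner_fraction = 1, model_id = "vbm1",
                       poor_moments = list(mu = c(-1.0, -1.0),
                                           sigma = c(0.3, 0.3)),
                       nonresponse_rate = c(0, 0))
  coh <- generate_cohort(cfg, seed = 12, task_args = list(trials_per_cue = 16))
  fits <- list()
  for (id in c("wsls", "vbm1"))
    fits[[id]] <- fit_hierarchical(coh$data, model_spec(id),
                                   mcmc = quick_mcmc(seed = 40 + nchar(id),
                                                     iter = 500, thin = 2))
  cmp <- compare_models(fits, n_boot = 3000, seed = 7)
  expect_equal(cmp$model[1], "wsls")
})
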