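test_that("delta-rule update matches direct substitution and contracts", {
  expect_equal(update_value(0.5, 1, alpha = 0.1), 0.55)
  expect_equal(update_value(0.2, 0, alpha = 0.5), 0.1)
  expect_equal(update_value(0, 1, alpha = 0.5, rho = 10), 5)
  # iterating under a constant outcome converges to rho * outcome
  for (case in list(c(a = 0.3, rho = 1, out = 1), c(a = 0.05, rho = 7, out = 1),
                    c(a = 0.9, rho = 2, out = -1))) {
    v <- 0.4
    for (i in 1:400)
      v <- unname(update_value(v, case[["out"]], case[["a"]], case[["rho"]]))
    expect_equal(v, unname(case[["rho"]] * case[["out"]]), tolerance = 1e-6)
  }
  expect_error(update_value(0, 1, alpha = 1), "alpha")
  expect_error(update_value(0, 1, alpha = 0), "alpha")
  expect_error(update_value(0, 1, alpha = 0.5, rho = -1), "rho")
})

test_that("softmax pair probabilities normalize, symmetrize and match closed forms", {
  expect_equal(choice_prob(1, 1, 5), 0.5)
  expect_equal(choice_prob(1, 0, 0), 0.5)
  expect_equal(choice_prob(1, 0, log(3)), 0.75)
  set.seed(4)
  for (i in 1:50) {
    v <- rnorm(2, sd = 3); tau <- runif(1, 0, 20)
    p1 <- choice_prob(v[1], v[2], tau)
    expect_equal(p1 + choice_prob(v[2], v[1], tau), 1)
    expect_gt(p1, 0); expect_lt(p1, 1)
  }
  # large value differences stay finite via the difference form
  expect_equal(choice_prob(1e4, -1e4, 20), 1)
  expect_error(choice_prob(Inf, 0, 1), "non-finite")
})

test_that("heuristic weight updates follow win-stay / lose-shift rules", {
  expect_equal(update_heuristic(c(0.5, 0.5), 1, "ws"), c(1, 0))
  expect_equal(update_heuristic(c(0.5, 0.5), 1, "wsls"), c(1, 0))
  expect_equal(update_heuristic(c(1, 0), 0, "wsls"), c(0, 1))
  expect_equal(update_heuristic(c(1, 0), 0, "ws"), c(0.5, 0.5))
  expect_error(update_heuristic(c(0.5, 0.5), 1, "greedy"))
  expect_error(update_heuristic(c(2, 0), 1, "ws"), "weights")
})

test_that("model registry encodes the ten variants correctly", {
  expect_equal(model_spec("vbm1")$params$name, c("alpha", "tau"))
  expect_equal(model_spec("vbm2")$params$name, c("alpha_imm", "alpha_del", "tau"))
  expect_equal(model_spec("vbm3")$params$name, c("alpha", "tau_imm", "tau_del"))
  expect_equal(model_spec("vbm8")$params$name,
               c("alpha_imm", "alpha_del", "rho_imm", "rho_del"))
  expect_equal(model_spec("ws")$params$name, "tau_strategy")
  expect_equal(model_spec("vbm5")$family, "outcome_sensitivity")
  expect_error(model_spec("vbm9"))
  # bounds: alpha in (0,1), everything else (0,20)
  s <- model_spec("vbm4")
  expect_equal(s$params$upper, c(1, 1, 20, 20))
})

test_that("simulated agents reproduce the reference R oracle trial-for-trial", {
  task <- generate_task(seed = 31)
  cases <- list(
    list(id = "vbm1", pars = list(alpha = 0.15, tau = 6)),
    list(id = "vbm3", pars = list(alpha = 0.08, tau_imm = 4, tau_del = 14)),
    list(id = "vbm7", pars = list(alpha = 0.2, rho_imm = 3, rho_del = 9)),
    list(id = "wsls", pars = list(tau_strategy = 2.5)),
    list(id = "ws",   pars = list(tau_strategy = 4)))
  for (cs in cases) {
    d <- simulate_agent(task, cs$pars, model_spec(cs$id), seed = 99)
    expect_equal(d$p_contingent,
                 reference_probs(d, cs$pars, cs$id), tolerance = 1e-12)
    # and the likelihood path agrees with the simulator's probabilities
    pars_df <- cbind(data.frame(subject_id = "sim", wave = 1), cs$pars)
    ll <- pointwise_loglik(d, pars_df, model_spec(cs$id))
    p_obs <- ifelse(d$choice == "contingent", d$p_contingent,
                    1 - d$p_contingent)
    expect_equal(exp(ll), p_obs, tolerance = 1e-12)
  }
})

test_that("an agent with a vanishing learning rate stays at chance", {
  task <- generate_task(seed = 5)
  d <- simulate_agent(task, list(alpha = 1e-12, tau = 10), model_spec("vbm1"),
                      seed = 6)
  expect_true(all(abs(d$p_contingent - 0.5) < 1e-9))
  accs <- replicate(60, {
    di <- simulate_agent(task, list(alpha = 1e-12, tau = 10), model_spec("vbm1"))
    mean(di$choice == "contingent")
  })
  expect_lt(abs(mean(accs) - 0.5), 0.02)
})

test_that("near-optimal agents reach the reference mean learning score", {
  task <- generate_task(seed = 8)
  set.seed(9)
  scores <- replicate(250, mean(
    simulate_agent(task, list(alpha = 0.29, tau = 19.8),
                   model_spec("vbm1"))$p_contingent))
  expect_equal(mean(scores), 0.965, tolerance = 0.01)
})

test_that("single-parameter collapse: vbm3 with equal taus equals vbm1", {
  task <- generate_task(seed = 13)
  d <- simulate_agent(task, list(alpha = 0.1, tau = 9), model_spec("vbm1"),
                      seed = 14)
  p1 <- data.frame(subject_id = "sim", wave = 1, alpha = 0.1, tau = 9)
  p3 <- data.frame(subject_id = "sim", wave = 1, alpha = 0.1,
                   tau_imm = 9, tau_del = 9)
  expect_equal(pointwise_loglik(d, p1, model_spec("vbm1")),
               pointwise_loglik(d, p3, model_spec("vbm3")), tolerance = 1e-12)
  # same collapse for the split learning rate
  p2 <- data.frame(subject_id = "sim", wave = 1, alpha_imm = 0.1,
                   alpha_del = 0.1, tau = 9)
  expect_equal(pointwise_loglik(d, p1, model_spec("vbm1")),
               pointwise_loglik(d, p2, model_spec("vbm2")), tolerance = 1e-12)
})

test_that("pointwise log-likelihood has the stated structure", {
  # first trial of any subject is always at chance
  d1 <- manual_data("contingent", 1L)
  expect_equal(pointwise_loglik(d1, data.frame(subject_id = "s1", wave = 1,
                                               alpha = 0.3, tau = 7),
                                model_spec("vbm1")),
               log(0.5))
  # concatenating subjects concatenates their vectors in canonical order
  task <- generate_task(seed = 2)
  da <- simulate_agent(task, list(alpha = 0.1, tau = 5), model_spec("vbm1"),
                       seed = 3, subject_id = "a")
  db <- simulate_agent(task, list(alpha = 0.2, tau = 9), model_spec("vbm1"),
                       seed = 4, subject_id = "b")
  pars <- data.frame(subject_id = c("a", "b"), wave = 1,
                     alpha = c(0.1, 0.2), tau = c(5, 9))
  both <- pointwise_loglik(rbind(da, db), pars, model_spec("vbm1"))
  sep <- c(pointwise_loglik(da, pars[1, ], model_spec("vbm1")),
           pointwise_loglik(db, pars[2, ], model_spec("vbm1")))
  expect_equal(both, sep)
  expect_error(pointwise_loglik(manual_data("none", NA), pars[1, ],
                                model_spec("vbm1")), "non-response")
})

test_that("heuristic weight pairs stay on the three admissible states", {
  task <- generate_task(seed = 21)
  d <- simulate_agent(task, list(tau_strategy = 2), model_spec("wsls"),
                      seed = 22)
  # reconstruct weights: probabilities can only be plogis(tau * {-1, 0, 1})
  admissible <- plogis(2 * c(-1, 0, 1))
  expect_true(all(vapply(d$p_contingent, function(p)
    any(abs(p - admissible) < 1e-12), logical(1))))
})
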