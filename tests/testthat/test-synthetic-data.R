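test_that("task designs satisfy the counting invariants", {
  task <- generate_task(seed = 1)
  tr <- task$trials
  expect_equal(nrow(tr), 128)
  expect_equal(unname(table(tr$cue_id)), rep(32L, 4), ignore_attr = TRUE)
  per_block <- table(tr$cue_id, tr$block)
  expect_true(all(per_block == 8))
  expect_equal(rowSums(task$schedule), rep(28, 4))
  expect_lte(max(rle(tr$cue_id)$lengths), 3)
  expect_equal(sum(task$condition_map == "immediate"), 2)
  # versions rotate the condition assignment
  maps <- vapply(1:4, function(v)
    paste(generate_task(version = v, seed = 2)$condition_map, collapse = ","),
    character(1))
  expect_equal(length(unique(maps)), 4)
  expect_error(generate_task(version = 5), "version")
  expect_error(generate_task(trials_per_cue = 30, n_blocks = 4), "divisible")
})

test_that("full contingency never rewards the noncontingent option", {
  task <- generate_task(contingency = 1, seed = 3)
  expect_true(all(task$schedule == 1))
  d <- simulate_agent(task, list(alpha = 0.3, tau = 2), model_spec("vbm1"),
                      seed = 4)
  expect_true(all(d$reward[d$choice == "noncontingent"] == 0))
  expect_true(all(d$reward[d$choice == "contingent"] == 1))
})

test_that("the realized reward schedule is exact regardless of choices", {
  cfg <- quick_config(n = 3)
  coh <- generate_cohort(cfg, seed = 9)
  d <- coh$data
  for (key in unique(paste(d$subject_id, d$wave))) {
    ds <- d[paste(d$subject_id, d$wave) == key, ]
    for (cue in unique(ds$cue_id)) {
      dc <- ds[ds$cue_id == cue, ]
      # reconstruct the contingent option's schedule from either choice
      sched <- ifelse(dc$choice == "contingent", dc$reward, 1 - dc$reward)
      expect_equal(sum(sched), 28)
    }
  }
})

test_that("cohorts honor retention, response and poor-learner settings", {
  cfg <- quick_config(n = 6)
  coh <- generate_cohort(cfg, seed = 5)
  counts <- table(coh$data$subject_id, coh$data$wave)
  expect_true(all(counts == 128))
  expect_true(all(coh$data$choice != "none"))
  expect_length(coh$poor_learners, 0)

  cfg2 <- cohort_config(n_subjects = 12, retention = 0.75,
                        poor_learner_fraction = 0.25,
                        nonresponse_rate = c(0, 0), model_id = "vbm3")
  coh2 <- generate_cohort(cfg2, seed = 6)
  expect_length(coh2$poor_learners, 3)        # exact deterministic count
  expect_length(unique(coh2$data$subject_id[coh2$data$wave == 2]), 9)
  expect_setequal(unique(coh2$params$model_id[
    coh2$params$subject_id %in% coh2$poor_learners]), "wsls")
})

test_that("non-responses appear at the configured per-wave rates", {
  cfg <- cohort_config(n_subjects = 50, retention = 1,
                       poor_learner_fraction = 0, model_id = "vbm1",
                       nonresponse_rate = c(0.0241, 0.0097))
  coh <- generate_cohort(cfg, seed = 31)
  cleaned <- drop_nonresponses(coh$data)
  excl <- attr(cleaned, "excluded")
  expect_equal(unname(excl["1"]), 0.0241, tolerance = 0.25)
  expect_equal(unname(excl["2"]), 0.0097, tolerance = 0.4)
})

test_that("true parameters hit the configured moments and correlation", {
  cfg <- cohort_config(model_id = "vbm3")
  tp <- draw_true_params(cfg, n = 1500, seed = 3)
  targets <- list(alpha = c(0.02, 0.05), tau_imm = c(14.6, 16.2),
                  tau_del = c(14.8, 16.5))
  sds <- list(alpha = c(0.02, 0.04), tau_imm = c(2.04, 2.37),
              tau_del = c(2.37, 2.21))
  for (pn in names(targets)) for (w in 1:2) {
    x <- tp$value[tp$parameter == pn & tp$wave == w]
    se <- sds[[pn]][w] / sqrt(length(x))
    expect_lt(abs(mean(x) - targets[[pn]][w]), 3 * se)
    expect_equal(sd(x), sds[[pn]][w], tolerance = 0.1)
  }
  # cross-wave correlation of unconstrained effects: configured value
  z1 <- tp$z[tp$parameter == "alpha" & tp$wave == 1]
  z2 <- tp$z[tp$parameter == "alpha" & tp$wave == 2]
  expect_equal(cor(z1, z2), 0.5, tolerance = 0.08)

  cfg0 <- cohort_config(model_id = "vbm1", cross_wave_cor = 0)
  tp0 <- draw_true_params(cfg0, n = 500, seed = 4)
  r0 <- cor(tp0$z[tp0$parameter == "tau" & tp0$wave == 1],
            tp0$z[tp0$parameter == "tau" & tp0$wave == 2])
  expect_lt(abs(r0), 0.1)
  expect_error(cohort_config(cross_wave_cor = 1.2), "cross_wave_cor")
})

test_that("trial records round-trip losslessly through CSV", {
  coh <- generate_cohort(cohort_config(n_subjects = 3, retention = 0.7,
                                       poor_learner_fraction = 1 / 3,
                                       model_id = "vbm3"), seed = 8)
  path <- tempfile(fileext = ".csv")
  write_trials(coh$data, path)
  back <- read_trials(path)
  expect_equal(back$choice, coh$data$choice)
  expect_equal(back$reward, coh$data$reward)
  expect_equal(back$p_contingent, coh$data$p_contingent, tolerance = 1e-12)
  expect_s3_class(back, "choice_data")
  path2 <- tempfile(fileext = ".csv")
  write_true_params(coh, path2)
  tp <- read.csv(path2)
  expect_setequal(names(tp), c("subject_id", "wave", "model_id",
                               "parameter", "value"))
})
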