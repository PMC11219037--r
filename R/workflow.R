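#' Two-step model development and selection workflow
#'
#' Reproduces the sequential comparison design: step 1 pits the
#' baseline value-based model against the two heuristic strategy models
#' (`vbm1`, `ws`, `wsls`); step 2 compares the eight value-based
#' variants (`vbm1`-`vbm8`).  Every model is fitted hierarchically over
#' both waves; non-converged fits stay in the tables flagged but are
#' excluded from the pseudo-BMA+ weight normalization.
#'
#' @param data A `choice_data` frame cleaned of non-responses.
#' @param mcmc An [mcmc_config()].
#' @param n_boot Bayesian bootstrap draws for the weights.
#' @param seed Optional integer master seed (chains and bootstrap draw
#'   named sub-seeds).
#' @param step Run `"both"` (default), `"1"` or `"2"`.
#' @return An `rlwaves_twostep` list: `step1` and `step2` comparison
#'   tables, `winner` (step-2 winning model id) and `winner_fit`.
#' @export
run_two_step_comparison <- function(data, mcmc = mcmc_config(),
                                    n_boot = 100000, seed = NULL,
                                    step = c("both", "1", "2")) {
  step <- match.arg(step)
  data <- as_choice_data(data)
  fit_one <- function(id)
    fit_hierarchical(data, model_spec(id),
                     mcmc = within_seed(mcmc, stage_seed(seed, paste0("fit_", id))))
  out <- list(step1 = NULL, step2 = NULL, winner = NULL, winner_fit = NULL)
  fits2 <- NULL
  if (step %in% c("both", "1")) {
    fits1 <- setNames(lapply(c("vbm1", "ws", "wsls"), fit_one),
                      c("vbm1", "ws", "wsls"))
    out$step1 <- compare_models(fits1, n_boot = n_boot,
                                seed = stage_seed(seed, "boot1"))
  }
  if (step %in% c("both", "2")) {
    ids <- paste0("vbm", 1:8)
    fits2 <- setNames(lapply(ids, fit_one), ids)
    out$step2 <- compare_models(fits2, n_boot = n_boot,
                                seed = stage_seed(seed, "boot2"))
    out$winner <- out$step2$model[1]
    out$winner_fit <- fits2[[out$winner]]
  }
  class(out) <- "rlwaves_twostep"
  out
}

#' @export
print.rlwaves_twostep <- function(x, ...) {
  if (!is.null(x$step1)) { cat("Step 1:\n"); print(x$step1) }
  if (!is.null(x$step2)) { cat("Step 2:\n"); print(x$step2) }
  if (!is.null(x$winner)) cat("Winning model:", x$winner, "\n")
  invisible(x)
}

#' Render a markdown analysis report
#'
#' Collects whatever run artifacts are supplied - comparison tables,
#' a learning-score map optimum, one-step-ahead accuracy, recovery
#' results - into a plain markdown report; missing sections are listed
#' rather than failing.
#'
#' @param path Output `.md` file.
#' @param comparison An `rlwaves_twostep` or `rlwaves_compare` (optional).
#' @param map An `rlwaves_map` (optional).
#' @param osa A [one_step_ahead()] result (optional).
#' @param recovery An `rlwaves_recovery` (optional).
#' @param title Report title.
#' @return `path`, invisibly.
#' @export
make_report <- function(path, comparison = NULL, map = NULL, osa = NULL,
                        recovery = NULL, title = "rlwaves run report") {
  lines <- c(paste("#", title), "")
  missing <- character(0)
  tab_md <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.3f", x))
    c(paste("|", paste(names(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|")))
  }
  if (!is.null(comparison)) {
    lines <- c(lines, "## Model comparison", "")
    if (inherits(comparison, "rlwaves_twostep")) {
      if (!is.null(comparison$step1))
        lines <- c(lines, "### Step 1: heuristic vs value-based", "",
                   tab_md(comparison$step1), "")
      if (!is.null(comparison$step2))
        lines <- c(lines, "### Step 2: value-based variants", "",
                   tab_md(comparison$step2), "",
                   paste("Winning model:", comparison$winner), "")
    } else {
      lines <- c(lines, tab_md(comparison), "")
    }
  } else missing <- c(missing, "model comparison")
  if (!is.null(map)) {
    opt <- find_optimum(map)
    lines <- c(lines, "## Learning-score map", "",
               sprintf("Grid %d x %d, %d replicates/cell.",
                       length(map$alpha), length(map$tau), map$reps),
               sprintf("Smoothed optimum: alpha = %.3f, tau = %.2f, score = %.1f%%.",
                       opt$smoothed$alpha, opt$smoothed$tau,
                       100 * opt$smoothed$score),
               sprintf("Raw optimum: alpha = %.3f, tau = %.2f, score = %.1f%%.",
                       opt$raw$alpha, opt$raw$tau, 100 * opt$raw$score), "")
  } else missing <- c(missing, "learning-score map")
  if (!is.null(osa)) {
    lines <- c(lines, "## One-step-ahead validation", "",
               paste0("Predictive accuracy: ",
                      paste(sprintf("wave %s = %.1f%%", names(osa$accuracy),
                                    100 * osa$accuracy), collapse = ", "),
                      sprintf(" (overall %.1f%%).", 100 * osa$overall)), "")
  } else missing <- c(missing, "one-step-ahead validation")
  if (!is.null(recovery)) {
    lines <- c(lines, "## Parameter recovery", "",
               tab_md(recovery$per_parameter), "")
  } else missing <- c(missing, "parameter recovery")
  if (length(missing))
    lines <- c(lines, "## Missing sections", "",
               paste("-", missing), "")
  writeLines(lines, path)
  invisible(path)
}
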