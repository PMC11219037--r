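#' Simulation-based learning-score map
#'
#' Tiles the (learning rate, inverse temperature) plane and simulates,
#' per cell, `reps` replicate agents of the single-alpha single-tau
#' value-based model playing the task on fresh exact reward schedules.
#' A replicate's learning score is its mean latent contingent-choice
#' probability over all trials; the cell stores the Monte-Carlo mean
#' and its standard error.  The default 100 x 100 grid spans the open
#' parameter ranges with 10,000 combinations.
#'
#' @param alpha_grid,tau_grid Grid values (defaults: 100 evenly spaced
#'   points over (0.005, 0.995) and (0.1, 19.9)).
#' @param reps Replicates per cell (default 200).
#' @param n_cues,trials_per_cue,contingency Task geometry (defaults: 4
#'   cues x 32 trials at 87.5% contingency).
#' @param seed Optional integer seed.
#' @return An `rlwaves_map` list: `alpha`, `tau`, `score` (alpha x tau
#'   matrix), `se`, `reps`.
#' @export
learning_score_map <- function(alpha_grid = seq(0.005, 0.995, length.out = 100),
                               tau_grid = seq(0.1, 19.9, length.out = 100),
                               reps = 200, n_cues = 4, trials_per_cue = 32,
                               contingency = 0.875, seed = NULL) {
  if (reps < 1) stop("reps must be >= 1")
  if (any(alpha_grid < 0 | alpha_grid > 1) || any(tau_grid < 0))
    stop("grid values outside parameter bounds")
  maybe_set_seed(seed)
  n_reward <- round(contingency * trials_per_cue)
  out <- cpp_learning_map(alpha_grid, tau_grid, as.integer(reps),
                          as.integer(n_cues), as.integer(trials_per_cue),
                          as.integer(n_reward))
  structure(list(alpha = alpha_grid, tau = tau_grid, score = out$score,
                 se = out$se, reps = reps, n_cues = n_cues,
                 trials_per_cue = trials_per_cue, contingency = contingency),
            class = "rlwaves_map")
}

#' Locate the optimal parameter combination on a map
#'
#' Returns the argmax cell of the raw map and of a 3x3 mean-filtered
#' (edge-renormalized) copy; smoothing suppresses Monte-Carlo jitter in
#' the location of the optimum.  Exact ties resolve to the first cell
#' in (alpha, tau) lexicographic order with a degeneracy warning.
#'
#' @param map An `rlwaves_map`.
#' @return List with `raw` and `smoothed`, each `(alpha, tau, score)`,
#'   where the smoothed entry reports the smoothed score at the
#'   smoothed argmax.
#' @export
find_optimum <- function(map) {
  stopifnot(inherits(map, "rlwaves_map"))
  if (!length(map$score)) stop("map is empty")
  pick <- function(M) {
    best <- max(M)
    hits <- which(M == best, arr.ind = TRUE)
    if (nrow(hits) > 1) {
      warning("degenerate map: ", nrow(hits), " cells tie at the maximum")
      hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    }
    list(alpha = map$alpha[hits[1, 1]], tau = map$tau[hits[1, 2]],
         score = best)
  }
  sm <- smooth_3x3(map$score)
  list(raw = pick(map$score), smoothed = pick(sm))
}

# 3x3 mean filter with edge renormalization (cells average only the
# neighbours that exist).
smooth_3x3 <- function(M) {
  n <- nrow(M); m <- ncol(M)
  padsum <- matrix(0, n, m)
  cnt <- matrix(0, n, m)
  for (di in -1:1) for (dj in -1:1) {
    si <- max(1, 1 + di):min(n, n + di)
    sj <- max(1, 1 + dj):min(m, m + dj)
    ti <- si - di; tj <- sj - dj
    padsum[ti, tj] <- padsum[ti, tj] + M[si, sj]
    cnt[ti, tj] <- cnt[ti, tj] + 1
  }
  padsum / cnt
}

#' Score of the map cell nearest a parameter point
#'
#' @param map An `rlwaves_map`.
#' @param alpha,tau Query point.
#' @param smoothed Use the 3x3-smoothed surface (default FALSE).
#' @return The cell's mean learning score.
#' @export
score_at <- function(map, alpha, tau, smoothed = FALSE) {
  stopifnot(inherits(map, "rlwaves_map"))
  i <- which.min(abs(map$alpha - alpha))
  j <- which.min(abs(map$tau - tau))
  M <- if (smoothed) smooth_3x3(map$score) else map$score
  M[i, j]
}

#' Model-derived learning scores from a fitted model
#'
#' Rolls each subject-wave's latent values forward on the observed
#' choice-outcome history at the posterior-mean individual parameters
#' and averages the per-trial contingent-choice probability, split by
#' feedback-timing condition.  These scores summarize value-based
#' learning on the probability scale and feed downstream longitudinal
#' analyses.
#'
#' @param fit An `rlwaves_fit`.
#' @param data The fitted dataset (defaults to the data in the fit).
#' @param posterior `"mean"` (default: single evaluation at the
#'   posterior-mean parameters) or `"draws"` (average of the score over
#'   thinned posterior draws).
#' @param n_draws Draw count when `posterior = "draws"`.
#' @return Data frame `subject_id`, `wave`, `condition`, `score`.
#' @export
fitted_learning_scores <- function(fit, data = NULL,
                                   posterior = c("mean", "draws"),
                                   n_draws = 200) {
  stopifnot(inherits(fit, "rlwaves_fit"))
  posterior <- match.arg(posterior)
  if (is.null(data)) data <- fit$data
  data <- as_choice_data(data)
  if (!all(unique(data$subject_id) %in% fit$subjects))
    stop("dataset contains subjects absent from the fit")
  pn <- dimnames(fit$theta)[[5]]
  score_from <- function(pars) {
    p <- latent_p_contingent(data, pars, fit$spec)
    agg <- aggregate(p, by = list(subject_id = data$subject_id,
                                  wave = data$wave,
                                  condition = data$condition), FUN = mean)
    names(agg)[4] <- "score"
    agg[order(agg$subject_id, agg$wave, agg$condition), ]
  }
  if (posterior == "mean") {
    out <- score_from(individual_means(fit))
  } else {
    th <- fit$theta
    n_iter <- dim(th)[1]; n_chain <- dim(th)[2]
    take <- unique(round(seq(1, n_iter,
                             length.out = max(1, ceiling(n_draws / n_chain)))))
    acc <- NULL
    k <- 0
    for (ch in seq_len(n_chain)) for (it in take) {
      pars <- data.frame(subject_id = rep(dimnames(th)[[3]], 2),
                         wave = rep(1:2, each = dim(th)[3]),
                         stringsAsFactors = FALSE)
      for (p in seq_along(pn))
        pars[[pn[p]]] <- c(th[it, ch, , 1, p], th[it, ch, , 2, p])
      s <- score_from(pars)
      if (is.null(acc)) acc <- s else acc$score <- acc$score + s$score
      k <- k + 1
    }
    acc$score <- acc$score / k
    out <- acc
  }
  rownames(out) <- NULL
  out
}
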