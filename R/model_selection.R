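#' PSIS-LOO expected log pointwise predictive density
#'
#' Leave-one-out cross-validation from posterior draws via Pareto
#' smoothed importance sampling: per trial, the raw importance ratios
#' are the inverse likelihoods, their upper tail is replaced by expected
#' order statistics of a generalized Pareto distribution fitted to the
#' tail (empirical-Bayes Zhang-Stephens fit), weights are truncated at
#' the raw maximum, and the smoothed weights average the predictive
#' density.  The summary SE is `sqrt(n * var(pointwise))`; trials with
#' tail shape k > 0.7 are counted as unreliable.
#'
#' @param x An `rlwaves_fit`, or a draws-by-trials matrix of pointwise
#'   log-likelihoods.
#' @param ... Unused.
#' @return An `rlwaves_loo` list: `pointwise` (elpd and Pareto k per
#'   trial), `elpd` (sum), `se`, `lpd` (in-sample log pointwise
#'   predictive density), `n`, `n_bad_k`.
#' @export
elpd_loo <- function(x, ...) UseMethod("elpd_loo")

#' @export
elpd_loo.rlwaves_fit <- function(x, ...) {
  out <- elpd_loo(x$log_lik)
  out$model_id <- x$spec$model_id
  out
}

#' @export
elpd_loo.matrix <- function(x, ...) {
  if (any(!is.finite(x)))
    stop("non-finite log-likelihoods at trial(s): ",
         paste(head(which(apply(!is.finite(x), 2, any))), collapse = ", "))
  S <- nrow(x); n <- ncol(x)
  elpd_i <- numeric(n); k_i <- numeric(n)
  lpd_i <- apply(x, 2, logsumexp) - log(S)
  for (j in seq_len(n)) {
    sm <- psis_smooth(-x[, j])
    lw <- sm$lw
    elpd_i[j] <- logsumexp(lw + x[, j]) - logsumexp(lw)
    k_i[j] <- sm$k
  }
  structure(list(
    pointwise = data.frame(elpd = elpd_i, k = k_i, lpd = lpd_i),
    elpd = sum(elpd_i), se = sqrt(n * var(elpd_i)),
    mean = mean(elpd_i), lpd = sum(lpd_i),
    n = n, n_bad_k = sum(k_i > 0.7)),
    class = "rlwaves_loo")
}

#' @export
print.rlwaves_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO over %d trials: elpd = %.1f (SE %.1f), mean %.3f\n",
              x$n, x$elpd, x$se, x$mean))
  if (x$n_bad_k > 0)
    cat(sprintf("  %d trial(s) with Pareto k > 0.7\n", x$n_bad_k))
  invisible(x)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Pareto-smooth a vector of raw log importance weights.
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- min(ceiling(0.2 * S), ceiling(3 * sqrt(S)))
  if (M < 5 || length(unique(lw)) < 5)
    return(list(lw = lw, k = -Inf))  # degenerate weights need no smoothing
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exceed <- exp(lw[tail_ids]) - exp(cutoff)
  if (all(exceed <= 0)) return(list(lw = lw, k = -Inf))
  fit <- gpd_fit(exceed)
  if (!is.finite(fit$k)) return(list(lw = lw, k = fit$k))
  # replace tail by expected order statistics of the fitted GPD
  p <- (seq_len(M) - 0.5) / M
  qs <- gpd_quantile(p, fit$k, fit$sigma) + exp(cutoff)
  lw[tail_ids[order(lw[tail_ids])]] <- log(qs)
  lw <- pmin(lw, 0)  # truncate at the (normalized) raw maximum
  list(lw = lw, k = fit$k)
}

# Empirical-Bayes generalized Pareto fit (Zhang & Stephens 2009).
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / prior_bs / xstar
  prof <- vapply(theta, function(th) {
    k <- -mean(log1p(-th * x))
    n * (log(th / k) + k - 1)
  }, numeric(1))
  w <- exp(prof - max(prof))
  w <- w / sum(w)
  th_hat <- sum(theta * w)
  k <- -mean(log1p(-th_hat * x))
  list(k = k, sigma = k / th_hat)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

#' Pseudo-BMA+ model weights
#'
#' Model weights from pointwise elpd vectors, stabilized by the Bayesian
#' bootstrap: for each of `n_boot` Dirichlet(1,...,1) draws of trial
#' weights, every model's weighted elpd sum (scaled by n) is
#' softmax-normalized (log-sum-exp safe), and the final weight is the
#' mean over draws.
#'
#' @param pointwise List (one element per model) of equal-length
#'   pointwise elpd vectors, or of `rlwaves_loo` objects.
#' @param n_boot Bayesian bootstrap draws (default 100000).
#' @param seed Optional integer seed.
#' @return Named numeric weights summing to 1.
#' @export
pseudo_bma_plus <- function(pointwise, n_boot = 100000, seed = NULL) {
  pw <- lapply(pointwise, function(x)
    if (inherits(x, "rlwaves_loo")) x$pointwise$elpd else as.numeric(x))
  n <- unique(vapply(pw, length, integer(1)))
  if (length(n) != 1) stop("pointwise vectors are misaligned across models")
  K <- length(pw)
  if (K == 1) return(setNames(1, names(pointwise)))
  maybe_set_seed(seed)
  E <- do.call(cbind, pw)  # n x K
  wsum <- numeric(K)
  done <- 0
  chunk <- max(1, min(2000, n_boot))
  while (done < n_boot) {
    b <- min(chunk, n_boot - done)
    G <- matrix(stats::rexp(b * n), b, n)
    G <- G / rowSums(G)          # Dirichlet(1,...,1) rows
    Z <- (G %*% E) * n           # b x K weighted elpd sums
    Z <- Z - apply(Z, 1, max)
    W <- exp(Z)
    W <- W / rowSums(W)
    wsum <- wsum + colSums(W)
    done <- done + b
  }
  w <- wsum / n_boot
  names(w) <- names(pointwise)
  w / sum(w)
}

#' Compare fitted models
#'
#' Builds the model-comparison table: PSIS-LOO elpd (sum and per-trial
#' mean), differences to the best model with paired pointwise SEs, and
#' pseudo-BMA+ weights.  All fits must be on the identical dataset
#' (trial alignment is checked by count).  Fits flagged as
#' non-converged are kept in the table but excluded from the weight
#' normalization.
#'
#' @param fits Named list of `rlwaves_fit` (or `rlwaves_loo`) objects.
#' @param n_boot Bayesian bootstrap draws for the weights.
#' @param seed Optional integer seed.
#' @return An `rlwaves_compare` data frame sorted by elpd, columns
#'   `model`, `parameters`, `delta_elpd`, `delta_se`, `elpd_sum`,
#'   `elpd_mean`, `weight`, `n_bad_k`, `converged`.
#' @export
compare_models <- function(fits, n_boot = 100000, seed = NULL) {
  if (!length(fits)) stop("need at least one model")
  loos <- lapply(fits, function(f)
    if (inherits(f, "rlwaves_loo")) f else elpd_loo(f))
  labels <- lapply(fits, function(f)
    if (inherits(f, "rlwaves_fit")) f$spec$label else NA_character_)
  conv <- vapply(fits, function(f)
    if (inherits(f, "rlwaves_fit")) f$converged else TRUE, logical(1))
  if (is.null(names(loos)))
    names(loos) <- vapply(seq_along(loos), function(i)
      loos[[i]]$model_id %||% paste0("model", i), character(1))
  ns <- vapply(loos, function(l) l$n, numeric(1))
  if (length(unique(ns)) != 1)
    stop("models were evaluated on differing trial counts")
  elpd <- vapply(loos, function(l) l$elpd, numeric(1))
  best <- which.max(elpd)
  delta <- elpd - elpd[best]
  delta_se <- vapply(seq_along(loos), function(i) {
    d <- loos[[i]]$pointwise$elpd - loos[[best]]$pointwise$elpd
    sqrt(length(d) * var(d))
  }, numeric(1))
  w <- rep(0, length(loos))
  if (sum(conv) >= 1)
    w[conv] <- pseudo_bma_plus(loos[conv], n_boot = n_boot, seed = seed)
  out <- data.frame(
    model = names(loos),
    parameters = unlist(labels),
    delta_elpd = delta, delta_se = delta_se,
    elpd_sum = elpd,
    elpd_mean = vapply(loos, function(l) l$mean, numeric(1)),
    weight = w,
    n_bad_k = vapply(loos, function(l) l$n_bad_k, numeric(1)),
    converged = conv,
    stringsAsFactors = FALSE)
  out <- out[order(-out$elpd_sum), ]
  rownames(out) <- NULL
  attr(out, "pointwise") <- lapply(loos, function(l) l$pointwise$elpd)
  class(out) <- c("rlwaves_compare", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rlwaves_compare <- function(x, ...) {
  cat("Model comparison (PSIS-LOO, pseudo-BMA+):\n")
  print.data.frame(cbind(x[, c("model", "parameters")],
                         round(x[, c("delta_elpd", "delta_se", "elpd_sum",
                                     "elpd_mean", "weight")], 3),
                         x[, "converged", drop = FALSE]))
  if (any(!x$converged))
    cat("(non-converged fits carry zero pseudo-BMA+ weight)\n")
  invisible(x)
}

#' Write a comparison table as CSV
#'
#' @param x An `rlwaves_compare` table.
#' @param path Output path.
#' @export
write_comparison <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
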