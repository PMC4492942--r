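#' Fit a Bernoulli latent-class mixture to binary band profiles
#'
#' Model-based clustering of dominant MSAP profiles: samples are assigned to
#' one of `K` latent classes, each class carrying an independent per-locus
#' band-presence probability with a Beta(`prior_a`, `prior_b`) prior, and a
#' symmetric Dirichlet(`prior_conc`) prior on class weights. Fitting is by
#' collapsed Gibbs sampling over sample assignments. Because single-site
#' updates cannot escape a poor merge of well-separated clusters, each of
#' `n_restarts` independent restarts runs its own burn-in with the
#' assignment conditional annealed (inverse temperature ramped from
#' `anneal_start` to 1), and the restart ending with the highest
#' posterior-mean log-likelihood is continued through the recording phase.
#' The membership matrix `Q` records posterior assignment frequencies over
#' the recorded sweeps (label switching resolved by greedy matching of
#' component frequency vectors against the first recorded state). `loglik`
#' is the mean recorded log-likelihood of the data under component
#' frequencies sampled from their Beta full conditionals — the quantity
#' scanned by [evanno_delta_k()].
#'
#' Class labels are identifiable only up to permutation; compare partitions,
#' not labels.
#'
#' @param x a [band_matrix()] or 0/1 matrix.
#' @param K number of latent classes (1 to `nrow(x)`).
#' @param n_iter recording horizon: `n_iter - burn_in` sweeps are recorded
#'   (default 2000).
#' @param burn_in burn-in sweeps per restart (default 500).
#' @param seed RNG seed (required for reproducibility).
#' @param prior_a,prior_b Beta prior on presence probabilities (default 1, 1).
#' @param prior_conc Dirichlet concentration on class weights (default 1).
#' @param n_restarts independent annealed burn-in restarts (default 6).
#' @param anneal_start initial inverse temperature of the burn-in ramp
#'   (default 0.4; 1 disables annealing).
#' @return Object of class `"latent_class_fit"`: `Q` (sample x K, rows sum
#'   to 1), `loglik`, `K`, `n_iter`, `burn_in`, `seed`, `assignment` (modal
#'   class per sample).
#' @export
fit_latent_class <- function(x, K, n_iter = 2000, burn_in = 500, seed = NULL,
                             prior_a = 1, prior_b = 1, prior_conc = 1,
                             n_restarts = 6, anneal_start = 0.4) {
  m <- unclass(x)
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% c(0L, 1L))) stop("matrix must be binary 0/1")
  if (K > nrow(m)) stop("K exceeds the number of samples")
  if (!is.null(seed)) set.seed(seed)
  res <- gibbs_latent_class(m, as.integer(K), as.integer(n_iter),
                            as.integer(burn_in), prior_a, prior_b, prior_conc,
                            as.integer(n_restarts), anneal_start)
  Q <- res$Q
  rownames(Q) <- rownames(m)
  colnames(Q) <- paste0("class", seq_len(K))
  structure(list(Q = Q, loglik = res$loglik, K = K, n_iter = n_iter,
                 burn_in = burn_in, seed = seed,
                 assignment = max.col(Q, ties.method = "first")),
            class = "latent_class_fit")
}

#' @export
print.latent_class_fit <- function(x, ...) {
  cat(sprintf(
    "Bernoulli latent-class fit: K = %d, %d samples, mean loglik = %.2f\n",
    x$K, nrow(x$Q), x$loglik))
  cat("class sizes (modal assignment):",
      paste(tabulate(x$assignment, nbins = x$K), collapse = ", "), "\n")
  invisible(x)
}

#' Scan K with repeated latent-class fits
#'
#' Runs `runs_per_k` independently seeded Gibbs fits for each K in
#' `k_min:k_max` and collects the mean post-burn-in log-likelihoods, the
#' input to Evanno's delta-K. Per-run seeds are drawn once from the master
#' seed, so results are independent of execution order.
#'
#' @param x a [band_matrix()] or 0/1 matrix.
#' @param k_min,k_max K range (delta-K needs `k_max >= k_min + 2`).
#' @param runs_per_k independent runs per K (>= 2 for delta-K).
#' @param n_iter,burn_in,prior_a,prior_b,prior_conc,n_restarts,anneal_start
#'   passed to [fit_latent_class()].
#' @param seed master seed governing all runs.
#' @return Data frame of class `"run_likelihood_table"` with columns `K`,
#'   `run`, `loglik`, `seed`.
#' @export
run_k_scan <- function(x, k_min = 1, k_max = 10, runs_per_k = 10,
                       n_iter = 2000, burn_in = 500, seed = NULL,
                       prior_a = 1, prior_b = 1, prior_conc = 1,
                       n_restarts = 6, anneal_start = 0.4) {
  stopifnot(k_min >= 1, k_max >= k_min)
  if (!is.null(seed)) set.seed(seed)
  ks <- k_min:k_max
  run_seeds <- matrix(sample.int(.Machine$integer.max, length(ks) * runs_per_k),
                      nrow = length(ks))
  rows <- list()
  for (i in seq_along(ks)) {
    for (r in seq_len(runs_per_k)) {
      fit <- fit_latent_class(x, ks[i], n_iter = n_iter, burn_in = burn_in,
                              seed = run_seeds[i, r], prior_a = prior_a,
                              prior_b = prior_b, prior_conc = prior_conc,
                              n_restarts = n_restarts,
                              anneal_start = anneal_start)
      rows[[length(rows) + 1L]] <- data.frame(
        K = ks[i], run = r, loglik = fit$loglik, seed = run_seeds[i, r])
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("run_likelihood_table", class(out))
  out
}

#' Evanno delta-K model selection
#'
#' For each interior K of the scan, delta-K is the mean over runs of the
#' absolute second difference of the run log-likelihoods,
#' `|L_r(K+1) - 2 L_r(K) + L_r(K-1)|`, divided by the standard deviation of
#' `L(K)` across runs. The selected K is the interior argmax. Undefined at
#' the scan endpoints; an interior K with zero run-to-run standard deviation
#' yields `Inf`/`NaN` and is flagged.
#'
#' @param table a [run_k_scan()] result (or data frame with columns `K`,
#'   `run`, `loglik`); needs at least 2 runs per K and 3 consecutive K.
#' @return Object of class `"delta_k_result"`: data frame `table` with
#'   columns `K`, `mean_loglik`, `sd_loglik`, `delta_k`, plus `k_selected`.
#' @export
evanno_delta_k <- function(table) {
  stopifnot(all(c("K", "run", "loglik") %in% names(table)))
  ks <- sort(unique(table$K))
  if (length(ks) < 3L) stop("need at least three consecutive K values")
  if (any(diff(ks) != 1L)) stop("K values must be contiguous")
  runs <- table(table$K)
  if (any(runs < 2L)) {
    stop("need at least two runs per K (run-to-run sd is undefined otherwise)")
  }
  L <- tapply(table$loglik, table$K, identity)
  mean_L <- vapply(L, mean, 0)
  sd_L <- vapply(L, stats::sd, 0)
  delta <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)[-c(1, length(ks))]) {
    nr <- min(lengths(L[c(i - 1, i, i + 1)]))
    # pair runs across adjacent K; falls back to equal-length truncation
    sec <- abs(L[[i + 1]][seq_len(nr)] - 2 * L[[i]][seq_len(nr)] +
                 L[[i - 1]][seq_len(nr)])
    delta[i] <- mean(sec) / sd_L[i]
  }
  flagged <- is.infinite(delta) | is.nan(delta)
  interior <- !is.na(delta) & !flagged
  k_selected <- if (any(interior)) ks[interior][which.max(delta[interior])] else NA_integer_
  structure(list(
    table = data.frame(K = ks, mean_loglik = mean_L, sd_loglik = sd_L,
                       delta_k = delta, row.names = NULL),
    k_selected = k_selected,
    flagged_k = ks[flagged]
  ), class = "delta_k_result")
}

#' @export
print.delta_k_result <- function(x, ...) {
  cat("Evanno delta-K\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("selected K =", x$k_selected, "\n")
  if (length(x$flagged_k)) {
    cat("delta-K undefined (zero run sd) at K =",
        paste(x$flagged_k, collapse = ", "), "\n")
  }
  invisible(x)
}
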