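#' One-level analysis of molecular variance (AMOVA)
#'
#' Excoffier-style partition of molecular variance from pairwise squared
#' distances, with a permutation test on the fixation index Phi-st.
#'
#' With N samples in G populations and squared pairwise distances d2:
#' \deqn{SS_{total} = \frac{1}{N} \sum_{i<j} d^2_{ij}, \qquad
#'       SS_{within} = \sum_g \frac{1}{n_g} \sum_{i<j \in g} d^2_{ij}}
#' `SS_among = SS_total - SS_within`; `df_among = G - 1`,
#' `df_within = N - G`; the within component is
#' `sigma2_w = SS_within / df_within` and the among component
#' `sigma2_a = (SS_among/df_among - sigma2_w) / n0` with
#' `n0 = (N - sum(n_g^2)/N) / (G - 1)`. `Phi_st = sigma2_a /
#' (sigma2_a + sigma2_w)`. A negative among component is reported raw and
#' truncated at zero only for the percentage split. Significance: sample
#' labels are permuted `n_perm` times and
#' `p = (#\{Phi_perm >= Phi_obs\} + 1) / (n_perm + 1)`.
#'
#' Distances from [msap_dist()] with metric `"mismatch_sq"` are already
#' squared Euclidean and are used as-is; `"jaccard"` distances are squared
#' first (the usual convention when feeding a non-Euclidean coefficient into
#' the variance framework).
#'
#' @param d a `dist` from [msap_dist()], or any `dist` (then assumed already
#'   squared unless `squared = FALSE`).
#' @param populations population labels: a [popmap()] or a vector (named by
#'   sample, or in `d`'s label order).
#' @param n_perm number of label permutations (0 skips the test).
#' @param seed RNG seed for the permutations; recorded in the result.
#' @param squared override the metric-based choice of whether `d` already
#'   holds squared distances.
#' @return Object of class `"msap_amova"`.
#' @export
msap_amova <- function(d, populations, n_perm = 9999, seed = NULL,
                       squared = NULL) {
  stopifnot(inherits(d, "dist"))
  labels <- attr(d, "Labels")
  n <- attr(d, "Size")
  pop <- amova_labels(populations, labels, n)
  if (length(unique(pop)) < 2L) stop("need at least two populations")
  if (n < 3L) stop("need at least three samples")
  if (is.null(squared)) {
    metric <- attr(d, "metric")
    squared <- is.null(metric) || metric == "mismatch_sq"
  }
  if (n_perm < 0) stop("n_perm must be >= 1 (or 0 to skip the test)")
  D2 <- as.matrix(d)
  if (!squared) D2 <- D2^2
  fit <- amova_components(D2, pop)
  p_perm <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    phi_obs <- fit$phi_st
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      phi_b <- amova_components(D2, sample(pop))$phi_st
      if (phi_b >= phi_obs) exceed <- exceed + 1L
    }
    p_perm <- (exceed + 1) / (n_perm + 1)
  }
  structure(c(fit, list(p_perm = p_perm, n_perm = n_perm, seed = seed,
                        n_samples = n, n_populations = length(unique(pop)))),
            class = "msap_amova")
}

amova_labels <- function(populations, labels, n) {
  if (inherits(populations, "popmap") ||
      (is.data.frame(populations) && all(c("sample", "population") %in% names(populations)))) {
    pop <- populations$population[match(labels, populations$sample)]
    if (anyNA(pop)) {
      stop("samples absent from population map: ",
           paste(labels[is.na(pop)], collapse = ", "))
    }
    return(as.character(pop))
  }
  pop <- populations
  if (!is.null(names(pop)) && !is.null(labels)) {
    if (!all(labels %in% names(pop))) {
      stop("population vector does not name all samples")
    }
    pop <- pop[labels]
  }
  if (length(pop) != n) stop("population labels do not match distance size")
  as.character(pop)
}

# Core sums-of-squares / variance-component computation on a squared-distance
# matrix. Kept free of S3 plumbing so the permutation loop stays cheap.
amova_components <- function(D2, pop) {
  n <- nrow(D2)
  groups <- unique(pop)
  G <- length(groups)
  ss_total <- sum(D2) / (2 * n)           # full matrix double-counts pairs
  ss_within <- 0
  n_g <- numeric(G)
  for (gi in seq_along(groups)) {
    idx <- which(pop == groups[gi])
    n_g[gi] <- length(idx)
    if (n_g[gi] > 1L) {
      ss_within <- ss_within + sum(D2[idx, idx]) / (2 * n_g[gi])
    }
  }
  ss_among <- ss_total - ss_within
  df_among <- G - 1L
  df_within <- n - G
  sigma2_w <- ss_within / df_within
  n0 <- (n - sum(n_g^2) / n) / df_among
  sigma2_a <- (ss_among / df_among - sigma2_w) / n0
  total_var <- sigma2_a + sigma2_w
  if (total_var <= 0) {
    pct_among <- pct_within <- NA_real_
    phi <- NA_real_
  } else {
    phi <- sigma2_a / total_var
    a_trunc <- max(sigma2_a, 0)
    pct_among <- 100 * a_trunc / (a_trunc + sigma2_w)
    pct_within <- 100 - pct_among
  }
  list(df_among = df_among, df_within = df_within,
       ss_among = ss_among, ss_within = ss_within, ss_total = ss_total,
       sigma2_a = sigma2_a, sigma2_w = sigma2_w,
       percent_among = pct_among, percent_within = pct_within,
       phi_st = phi, n0 = n0)
}

#' @export
print.msap_amova <- function(x, ...) {
  cat("One-level AMOVA\n")
  tab <- data.frame(
    source = c("Among populations", "Within populations", "Total"),
    df = c(x$df_among, x$df_within, x$df_among + x$df_within),
    SS = c(x$ss_among, x$ss_within, x$ss_total),
    sigma2 = c(x$sigma2_a, x$sigma2_w, x$sigma2_a + x$sigma2_w),
    percent = c(x$percent_among, x$percent_within, 100)
  )
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("Phi_st = %.4f", x$phi_st))
  if (!is.na(x$p_perm)) {
    cat(sprintf(", p = %.4g (%d permutations)", x$p_perm, x$n_perm))
  }
  cat("\n")
  invisible(x)
}

#' Serialise an AMOVA result to JSON
#'
#' @param x an [msap_amova()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_amova_json <- function(x, path) {
  stopifnot(inherits(x, "msap_amova"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
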