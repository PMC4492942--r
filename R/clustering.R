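#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomeration (arithmetic means weighted by cluster
#' sizes), returned as a rooted ultrametric `phylo` tree whose cophenetic
#' distances reproduce the input exactly when the input is itself
#' ultrametric. Leaf-to-root depth is half the joining distance, so two
#' samples at distance 2 sit on branches of length 1.
#'
#' @param d a `dist` (typically Jaccard distances from [msap_dist()]).
#' @return An [ape::as.phylo()] tree of class `"phylo"`.
#' @export
upgma <- function(d) {
  stopifnot(inherits(d, "dist"), attr(d, "Size") >= 2)
  hc <- stats::hclust(d, method = "average")
  ape::as.phylo(hc)
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centres the squared distances (Gower transform) and
#' eigendecomposes; coordinates are eigenvectors scaled by the square roots
#' of the positive eigenvalues (via [stats::cmdscale()]). Negative
#' eigenvalues — possible for non-Euclidean coefficients such as Jaccard —
#' are dropped and counted. Explained-variance percentages (`C1`, `C2`, ...)
#' are taken over the positive eigenvalues.
#'
#' `mismatch_sq` distances are square-rooted before embedding, since they
#' are already squared Euclidean.
#'
#' @param d a `dist` from [msap_dist()] (or any `dist`).
#' @return Object of class `"msap_pcoa"`: `points` (sample x axis), `eig`,
#'   `explained` (percentages), `n_negative`, `degenerate` flag.
#' @export
msap_pcoa <- function(d) {
  stopifnot(inherits(d, "dist"), attr(d, "Size") >= 2)
  if (identical(attr(d, "metric"), "mismatch_sq")) d <- sqrt(d)
  n <- attr(d, "Size")
  res <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- res$eig
  tol <- max(abs(eig)) * 1e-9
  pos <- eig > tol
  n_negative <- sum(eig < -tol)
  degenerate <- !any(pos)
  pts <- res$points
  if (!degenerate) {
    k <- min(ncol(pts), sum(pos))
    pts <- pts[, seq_len(k), drop = FALSE]
    explained <- 100 * eig[pos] / sum(eig[pos])
  } else {
    pts <- matrix(0, n, 0, dimnames = list(attr(d, "Labels"), NULL))
    explained <- numeric(0)
  }
  if (ncol(pts) > 0) colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  structure(list(points = pts, eig = eig, explained = explained,
                 n_negative = n_negative, degenerate = degenerate),
            class = "msap_pcoa")
}

#' @export
print.msap_pcoa <- function(x, ...) {
  if (x$degenerate) {
    cat("PCoA: degenerate (all eigenvalues zero)\n")
    return(invisible(x))
  }
  cat(sprintf("PCoA: %d samples, %d positive axes (%d negative eigenvalues dropped)\n",
              nrow(x$points), length(x$explained), x$n_negative))
  show <- utils::head(x$explained, 3)
  cat(paste(sprintf("C%d = %.1f%%", seq_along(show), show), collapse = ", "), "\n")
  invisible(x)
}

#' Group centroids and 1-sd dispersion ellipses on the first two axes
#'
#' Per group: the centroid of its samples and the ellipse described by the
#' eigen-structure of the group's 2x2 coordinate covariance (population
#' convention, dividing by n), so axis lengths are the standard deviations
#' along the principal dispersion directions. The long axis points along the
#' direction of maximum dispersion. Singleton (or point-mass) groups get a
#' zero-axis ellipse and are flagged.
#'
#' @param coords sample x axis coordinate matrix (at least two columns),
#'   e.g. `points` from [msap_pcoa()].
#' @param groups group labels, named by sample or in row order.
#' @return Data frame with columns `group`, `n`, `centroid1`, `centroid2`,
#'   `major`, `minor`, `angle` (radians of the major axis), `degenerate`.
#' @export
group_dispersion <- function(coords, groups) {
  stopifnot(is.matrix(coords), ncol(coords) >= 2)
  if (!is.null(names(groups)) && !is.null(rownames(coords))) {
    groups <- groups[rownames(coords)]
  }
  stopifnot(length(groups) == nrow(coords))
  xy <- coords[, 1:2, drop = FALSE]
  out <- lapply(unique(groups), function(g) {
    pts <- xy[groups == g, , drop = FALSE]
    n <- nrow(pts)
    ctr <- colMeans(pts)
    cv <- crossprod(sweep(pts, 2, ctr)) / n
    e <- eigen(cv, symmetric = TRUE)
    lens <- sqrt(pmax(e$values, 0))
    deg <- n < 2 || all(lens < 1e-12)
    data.frame(group = g, n = n, centroid1 = ctr[1], centroid2 = ctr[2],
               major = lens[1], minor = lens[2],
               angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
               degenerate = deg, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Permutation test of group separation on a distance matrix
#'
#' Tests whether among-group differentiation (Phi-st) on the given distance
#' matrix exceeds what label permutations produce; a thin wrapper around the
#' AMOVA permutation machinery.
#'
#' @param d a `dist`.
#' @param groups group labels (vector or [popmap()]).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return Permutation p-value; the full [msap_amova()] result is attached
#'   as attribute `"amova"`.
#' @export
group_separation_test <- function(d, groups, n_perm = 9999, seed = NULL) {
  fit <- msap_amova(d, groups, n_perm = n_perm, seed = seed)
  structure(fit$p_perm, amova = fit)
}
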