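make_dist <- function(m, labels = NULL) {
  d <- stats::as.dist(m)
  if (!is.null(labels)) attr(d, "Labels") <- labels
  d
}

# random ultrametric matrix built by agglomerating random heights
random_ultrametric <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(rnorm(n * 3), n)
  rownames(pts) <- paste0("t", seq_len(n))
  hc <- stats::hclust(stats::dist(pts), method = "average")
  as.matrix(stats::cophenetic(hc))
}

test_that("UPGMA hand examples: pair midpoint and 3-leaf agglomeration", {
  d2 <- make_dist(matrix(c(0, 2, 2, 0), 2), c("A", "B"))
  tr <- upgma(d2)
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(unname(tr$edge.length), c(1, 1))

  # d(A,B)=2, d(A,C)=d(B,C)=4 -> ((A:1,B:1):1,C:2), cophenetic d(A,C)=4
  m3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- upgma(make_dist(m3))
  cd <- as.matrix(ape::cophenetic.phylo(tr3))
  expect_equal(cd["A", "B"], 2)
  expect_equal(cd["A", "C"], 4)
  expect_equal(cd["B", "C"], 4)
  # ultrametric: all root-to-tip depths equal
  depths <- ape::node.depth.edgelength(tr3)[1:3]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-9)
})

test_that("UPGMA cophenetic round-trip is exact on ultrametric inputs", {
  for (seed in 1:5) {
    n <- sample(4:16, 1)
    U <- random_ultrametric(n, seed)
    tr <- upgma(make_dist(U))
    cd <- as.matrix(ape::cophenetic.phylo(tr))[rownames(U), colnames(U)]
    expect_equal(cd, U, tolerance = 1e-9)
  }
})

test_that("UPGMA Newick round-trip preserves the cophenetic matrix", {
  ds <- random_dataset(n = 7, L = 12, seed = 19)
  tr <- upgma(msap_dist(ds$hpa, "jaccard"))
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, path)
  back <- ape::read.tree(path)
  cd1 <- as.matrix(ape::cophenetic.phylo(tr))
  cd2 <- as.matrix(ape::cophenetic.phylo(back))[rownames(cd1), colnames(cd1)]
  expect_equal(cd2, cd1, tolerance = 1e-9)
})

test_that("PCoA: two-point closed form and Euclidean reconstruction", {
  d <- make_dist(matrix(c(0, 3, 3, 0), 2), c("A", "B"))
  pc <- msap_pcoa(d)
  expect_equal(abs(unname(pc$points[, 1])), c(1.5, 1.5))
  expect_equal(pc$explained[1], 100)

  # planted Euclidean point cloud: distances reconstructed to 1e-9 and C1
  # matches the leading-variance share from direct eigen-analysis
  set.seed(6)
  pts <- cbind(rnorm(40, sd = 5), rnorm(40, sd = 2), rnorm(40, sd = 1))
  rownames(pts) <- paste0("p", 1:40)
  d0 <- stats::dist(pts)
  pc0 <- msap_pcoa(d0)
  expect_equal(as.matrix(stats::dist(pc0$points)), as.matrix(d0),
               tolerance = 1e-9, ignore_attr = TRUE)
  ev <- eigen(stats::cov(pts) * (39 / 40), symmetric = TRUE)$values
  expect_equal(pc0$explained[1], 100 * ev[1] / sum(ev), tolerance = 1e-6)
  expect_equal(pc0$n_negative, 0)

  # zero matrix: degenerate, flagged
  dz <- make_dist(matrix(0, 3, 3), c("a", "b", "c"))
  expect_true(msap_pcoa(dz)$degenerate)

  # explained percentages invariant to sample order
  ds <- random_dataset(n = 9, L = 10, seed = 25)
  e1 <- msap_pcoa(msap_dist(ds$hpa, "jaccard"))$explained
  perm <- sample(9)
  e2 <- msap_pcoa(msap_dist(band_matrix(unclass(ds$hpa)[perm, ], "HPA"),
                            "jaccard"))$explained
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("mismatch_sq distances are square-rooted before embedding", {
  ds <- random_dataset(n = 6, L = 8, seed = 30)
  pc_m <- msap_pcoa(msap_dist(ds$hpa, "mismatch_sq"))
  # embedding of binary profiles in Euclidean space is exact: reconstructed
  # squared distances equal the mismatch counts
  rec <- as.matrix(stats::dist(pc_m$points))^2
  expect_equal(rec, as.matrix(msap_dist(ds$hpa, "mismatch_sq")),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("group dispersion ellipses: closed forms and equivariance", {
  # identical points -> zero axes, flagged
  xy <- rbind(c(1, 1), c(1, 1), c(1, 1))
  rownames(xy) <- paste0("s", 1:3)
  gd <- group_dispersion(xy, rep("g", 3))
  expect_equal(gd$major, 0)
  expect_true(gd$degenerate)

  # points at (+-1, 0): population sd along x is 1, minor axis 0
  xy2 <- rbind(c(1, 0), c(-1, 0))
  rownames(xy2) <- c("a", "b")
  gd2 <- group_dispersion(xy2, rep("g", 2))
  expect_equal(gd2$major, 1)
  expect_equal(gd2$minor, 0)
  expect_equal(abs(cos(gd2$angle)), 1)  # major axis along x

  # rotation equivariance: centroids and orientations rotate together
  set.seed(12)
  pts <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), NULL))
  grp <- rep(c("g1", "g2"), each = 5)
  th <- pi / 5
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  g_orig <- group_dispersion(pts, grp)
  g_rot <- group_dispersion(pts %*% R, grp)
  expect_equal(g_rot$major, g_orig$major, tolerance = 1e-9)
  expect_equal(g_rot$minor, g_orig$minor, tolerance = 1e-9)
  expect_equal(unname(as.matrix(g_rot[, c("centroid1", "centroid2")])),
               unname(as.matrix(g_orig[, c("centroid1", "centroid2")]) %*% R),
               tolerance = 1e-9)
  # row-vector convention: pts %*% R rotates by -th
  ang_diff <- (g_rot$angle - g_orig$angle + th) %% pi
  expect_true(all(pmin(ang_diff, pi - ang_diff) < 1e-6))
})
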