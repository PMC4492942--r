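test_that("AMOVA reproduces the fully hand-computed 4-sample example", {
  # pops {s1=(1,0,0), s2=(1,1,0)} and {s3=(0,1,1), s4=(0,1,0)}:
  # d2 pairs: 1,3,2 | 2,1 | 1 -> SS_T=2.5, SS_W=1.0, SS_A=1.5,
  # sigma2_a = sigma2_w = 0.5, 50/50 split, Phi_st = 0.5
  m <- toy_matrix(rbind(c(1, 0, 0), c(1, 1, 0), c(0, 1, 1), c(0, 1, 0)), "MSP")
  pm <- toy_popmap(paste0("s", 1:4), c("P1", "P1", "P2", "P2"))
  fit <- msap_amova(msap_dist(m, "mismatch_sq"), pm, n_perm = 0)
  expect_equal(fit$ss_total, 2.5)
  expect_equal(fit$ss_within, 1.0)
  expect_equal(fit$ss_among, 1.5)
  expect_equal(fit$sigma2_a, 0.5)
  expect_equal(fit$sigma2_w, 0.5)
  expect_equal(fit$percent_among, 50)
  expect_equal(fit$phi_st, 0.5)
  expect_equal(fit$df_among, 1L)
  expect_equal(fit$df_within, 2L)
})

test_that("AMOVA equals the brute-force double-loop oracle on random data", {
  set.seed(13)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    L <- sample(2:4, 1)
    m <- toy_matrix(matrix(rbinom(n * L, 1, 0.5), n, L), "MSP")
    pop <- sample(paste0("P", 1:sample(2:3, 1)), n, replace = TRUE)
    if (length(unique(pop)) < 2) next
    d <- msap_dist(m, "mismatch_sq")
    fit <- msap_amova(d, setNames(pop, rownames(m)), n_perm = 0)
    oracle <- amova_oracle(as.matrix(d), pop)
    expect_equal(fit$ss_total, oracle$ss_total, tolerance = 1e-9)
    expect_equal(fit$ss_within, oracle$ss_within, tolerance = 1e-9)
    expect_equal(fit$sigma2_a, oracle$sigma2_a, tolerance = 1e-9)
    expect_equal(fit$sigma2_w, oracle$sigma2_w, tolerance = 1e-9)
    if (!is.na(fit$phi_st)) {
      expect_equal(fit$phi_st, oracle$phi_st, tolerance = 1e-9)
    }
  }
})

test_that("AMOVA sums of squares agree with vegan::adonis2", {
  ds <- random_dataset(n = 12, L = 10, n_pops = 3, seed = 21)
  d2 <- msap_dist(ds$msp, "mismatch_sq")
  fit <- msap_amova(d2, ds$popmap, n_perm = 0)
  pop <- factor(ds$popmap$population)
  ad <- vegan::adonis2(sqrt(as.matrix(d2)) ~ pop, permutations = 0)
  expect_equal(fit$ss_among, ad$SumOfSqs[1], tolerance = 1e-8)
  expect_equal(fit$ss_within, ad$SumOfSqs[2], tolerance = 1e-8)
})

test_that("AMOVA properties: relabeling invariance, degenerate cases, merging", {
  ds <- random_dataset(n = 8, L = 6, n_pops = 2, seed = 5)
  d <- msap_dist(ds$msp, "mismatch_sq")
  f1 <- msap_amova(d, ds$popmap, n_perm = 0)
  # reorder samples: same components
  perm <- sample(8)
  m2 <- band_matrix(unclass(ds$msp)[perm, ], "MSP")
  f2 <- msap_amova(msap_dist(m2, "mismatch_sq"),
                   setNames(ds$popmap$population, ds$popmap$sample)[rownames(m2)],
                   n_perm = 0)
  expect_equal(f2$phi_st, f1$phi_st)
  expect_equal(f2$ss_among, f1$ss_among)

  # maximal differentiation: identical within, different across
  m3 <- toy_matrix(rbind(c(1, 1), c(1, 1), c(0, 0), c(0, 0)), "MSP")
  pm3 <- toy_popmap(paste0("s", 1:4), c("A", "A", "B", "B"))
  f3 <- msap_amova(msap_dist(m3, "mismatch_sq"), pm3, n_perm = 0)
  expect_equal(f3$ss_total, 2)
  expect_equal(f3$ss_within, 0)
  expect_equal(f3$percent_among, 100)

  # all samples identical: zero variance flagged
  m4 <- toy_matrix(matrix(1, 4, 3), "MSP")
  f4 <- msap_amova(msap_dist(m4, "mismatch_sq"), pm3, n_perm = 0)
  expect_true(is.na(f4$percent_among))
  expect_true(is.na(f4$phi_st))

  # singleton population allowed (contributes 0 to SS_within)
  m5 <- random_dataset(n = 5, L = 6, seed = 31)$msp
  pm5 <- setNames(c("A", "A", "A", "A", "B"), rownames(m5))
  expect_silent(f5 <- msap_amova(msap_dist(m5, "mismatch_sq"), pm5, n_perm = 0))
  expect_equal(f5$df_among, 1L)

  # merging two populations never increases SS_among (brute force, N <= 6)
  set.seed(77)
  for (rep in 1:20) {
    n <- 6
    m6 <- matrix(rbinom(n * 4, 1, 0.5), n, 4,
                 dimnames = list(paste0("s", 1:n), paste0("L", 1:4)))
    pop3 <- sample(c("A", "B", "C"), n, replace = TRUE)
    if (length(unique(pop3)) < 3) next
    d6 <- msap_dist(band_matrix(m6, "MSP"), "mismatch_sq")
    ss3 <- msap_amova(d6, setNames(pop3, rownames(m6)), n_perm = 0)$ss_among
    merged <- ifelse(pop3 == "B", "A", pop3)
    ss2 <- msap_amova(d6, setNames(merged, rownames(m6)), n_perm = 0)$ss_among
    expect_lte(ss2, ss3 + 1e-9)
  }
})

test_that("permutation test: determinism, minimal p at maximal differentiation", {
  ds <- random_dataset(n = 10, L = 8, n_pops = 2, seed = 17)
  d <- msap_dist(ds$msp, "mismatch_sq")
  p1 <- msap_amova(d, ds$popmap, n_perm = 199, seed = 99)$p_perm
  p2 <- msap_amova(d, ds$popmap, n_perm = 199, seed = 99)$p_perm
  expect_identical(p1, p2)
  expect_error(msap_amova(d, ds$popmap, n_perm = -1), "n_perm")

  # two maximally differentiated pops of 2: only the 3 of C(4,2)=6 label
  # splits preserving the partition tie Phi_obs; exhaustively, the
  # permutation p concentrates near the achievable minimum
  m3 <- toy_matrix(rbind(c(1, 1), c(1, 1), c(0, 0), c(0, 0)), "MSP")
  pm3 <- toy_popmap(paste0("s", 1:4), c("A", "A", "B", "B"))
  p <- msap_amova(msap_dist(m3, "mismatch_sq"), pm3, n_perm = 999, seed = 1)$p_perm
  # P(random split ties Phi_obs) = 1/3 for 4 samples; p ~ 1/3, far below 1
  expect_lt(p, 0.45)
  expect_gt(p, 0.2)
})

test_that("group separation test wraps the AMOVA permutation machinery", {
  ds <- random_dataset(n = 10, L = 8, n_pops = 2, seed = 23)
  d <- msap_dist(ds$msp, "mismatch_sq")
  p <- group_separation_test(d, ds$popmap, n_perm = 99, seed = 3)
  fit <- attr(p, "amova")
  expect_s3_class(fit, "msap_amova")
  expect_identical(as.numeric(p), fit$p_perm)
})
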