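test_that("the isoschizomer truth table maps all four joint patterns", {
  expect_equal(classify_pattern(1, 1), "I")  # hemi-methylation, inner cytosine
  expect_equal(classify_pattern(1, 0), "O")  # hemi-methylation, outer cytosine
  expect_equal(classify_pattern(0, 1), "D")  # double-strand inner methylation
  expect_equal(classify_pattern(0, 0), "U")  # fully methylated or target absent
  expect_error(classify_pattern(2, 0), "0 or 1")
  expect_error(classify_pattern(c(1, 0), 1), "lengths")
})

test_that("encode/decode is a bijection on random matrices", {
  set.seed(42)
  for (rep in 1:20) {
    h <- rbinom(50, 1, runif(1, 0.1, 0.9))
    m <- rbinom(50, 1, runif(1, 0.1, 0.9))
    dec <- decode_state(classify_pattern(h, m))
    expect_identical(dec$hpa, as.integer(h))
    expect_identical(dec$msp, as.integer(m))
  }
  expect_error(decode_state("Z"), "unknown")
})

test_that("classify_dataset applies the truth table elementwise and round-trips", {
  hpa <- toy_matrix(matrix(c(1, 0), 1, 2), "HPA", "s1")
  msp <- toy_matrix(matrix(c(1, 1), 1, 2), "MSP", "s1")
  ds <- msap_dataset(hpa, msp, toy_popmap("s1", "P1"))
  st <- classify_dataset(ds)
  expect_equal(unname(unclass(st)[1, ]), c("I", "D"))

  ds0 <- random_dataset(n = 6, L = 8, seed = 7)
  st0 <- classify_dataset(ds0)
  dec <- decode_state(as.vector(unclass(st0)))
  expect_equal(matrix(dec$hpa, 6, 8), unclass(ds0$hpa)[, ], ignore_attr = TRUE)
  expect_equal(matrix(dec$msp, 6, 8), unclass(ds0$msp)[, ], ignore_attr = TRUE)

  # all-zero matrices classify as fully-methylated-or-absent everywhere
  z <- toy_matrix(matrix(0, 2, 2), "HPA")
  zm <- toy_matrix(matrix(0, 2, 2), "MSP")
  stz <- classify_dataset(msap_dataset(z, zm, toy_popmap(c("s1", "s2"), "P1")))
  expect_true(all(unclass(stz) == "U"))
})

test_that("locus partitioning: MSL evidence, inclusive 5% polymorphism boundary", {
  # 20 samples: locus 1 all hemi-inner; locus 2 has 19 I + 1 D
  h <- cbind(rep(1, 20), c(rep(1, 19), 0))
  m <- cbind(rep(1, 20), rep(1, 20))
  ds <- msap_dataset(toy_matrix(h, "HPA"), toy_matrix(m, "MSP"),
                     toy_popmap(paste0("s", 1:20), "P1"))
  cls <- partition_loci(classify_dataset(ds))
  # locus 1: single pattern, no O/D evidence -> NML, monomorphic
  expect_false(cls$is_msl[1])
  expect_false(cls$is_polymorphic[1])
  # locus 2: one D sample -> MSL; minor pattern at exactly 5% counts
  expect_true(cls$is_msl[2])
  expect_true(cls$is_polymorphic[2])
  expect_equal(cls$major_pattern_freq[2], 0.95)

  expect_equal(polymorphism_rate(cls), 0.5)
  expect_equal(polymorphism_rate(cls, "msl"), 1)
  expect_warning(r <- polymorphism_rate(cls[cls$is_msl, ][0, ], "msl"),
                 "undefined")
  expect_true(is.na(r))
})

test_that("partitioning is invariant under sample reordering", {
  ds <- random_dataset(n = 10, L = 12, seed = 3)
  st <- classify_dataset(ds)
  cls <- partition_loci(st)
  perm <- sample(nrow(st))
  st2 <- structure(unclass(st)[perm, ], class = class(st))
  expect_equal(partition_loci(st2), cls)
})

test_that("methylation level report: proportions per group sum to one", {
  # one group, 4 cells: I, I, O, D -> (0.5, 0.25, 0.25, 0)
  h <- matrix(c(1, 1, 1, 0), 2, 2, byrow = TRUE)
  m <- matrix(c(1, 1, 0, 1), 2, 2, byrow = TRUE)
  ds <- msap_dataset(toy_matrix(h, "HPA"), toy_matrix(m, "MSP"),
                     toy_popmap(c("s1", "s2"), "P1"))
  rep1 <- methylation_level_report(classify_dataset(ds),
                                   c(s1 = "g", s2 = "g"))
  expect_equal(unlist(rep1[1, c("I", "O", "D", "U")]), c(I = 0.5, O = 0.25, D = 0.25, U = 0))

  # rows always sum to 1 on random data, across several groups
  ds2 <- random_dataset(n = 9, L = 7, n_pops = 3, seed = 11)
  st2 <- classify_dataset(ds2)
  groups <- setNames(ds2$popmap$population, ds2$popmap$sample)
  rep2 <- methylation_level_report(st2, groups)
  expect_equal(rowSums(rep2[, c("I", "O", "D", "U")]), rep(1, 3),
               tolerance = 1e-12, ignore_attr = TRUE)

  # ungrouped sample is an error
  expect_error(methylation_level_report(st2, groups[-1]), "ungrouped")
})

test_that("relative methylation series follows the category mapping", {
  # one sample per state-mix: equal counts of the four states
  h <- matrix(c(1, 1, 0, 0), 1, 4)
  m <- matrix(c(1, 0, 1, 0), 1, 4)
  ds <- msap_dataset(toy_matrix(h, "HPA"), toy_matrix(m, "MSP"),
                     toy_popmap("s1", "P1"))
  ser <- relative_methylation_series(classify_dataset(ds))
  expect_equal(ser$methylated_total, 0.75)
  expect_equal(ser$hemi_inner, 0.25)
  expect_equal(ser$cg, 0.25)
  expect_equal(ser$cng, 0.25)

  # all hemi-inner -> hemi fraction 1; identical samples give identical rows
  h2 <- matrix(1, 2, 3); m2 <- matrix(1, 2, 3)
  ds2 <- msap_dataset(toy_matrix(h2, "HPA"), toy_matrix(m2, "MSP"),
                      toy_popmap(c("s1", "s2"), "P1"))
  ser2 <- relative_methylation_series(classify_dataset(ds2))
  expect_equal(ser2$hemi_inner, c(1, 1))
  expect_equal(ser2[1, -1], ser2[2, -1], ignore_attr = TRUE)
})

test_that("state matrix export writes codes plus a legend sidecar", {
  ds <- random_dataset(n = 4, L = 3, seed = 5)
  st <- classify_dataset(ds)
  path <- withr::local_tempfile(fileext = ".csv")
  write_state_matrix(st, path)
  back <- utils::read.csv(path, row.names = 1)
  expect_equal(as.matrix(back), unclass(st)[, ], ignore_attr = TRUE)
  legend <- jsonlite::read_json(paste0(path, ".legend.json"))
  expect_named(legend, c("I", "O", "D", "U"))
})
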