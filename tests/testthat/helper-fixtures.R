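# Small in-code fixtures shared across test files.

toy_matrix <- function(m, enzyme = "HPA", samples = NULL, loci = NULL) {
  m <- as.matrix(m)
  rownames(m) <- samples %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- loci %||% paste0("L", seq_len(ncol(m)))
  band_matrix(m, enzyme)
}

toy_popmap <- function(samples, populations) {
  popmap(data.frame(sample = samples, population = populations,
                    stringsAsFactors = FALSE))
}

# A random paired dataset with no particular structure.
random_dataset <- function(n = 8, L = 6, n_pops = 2, seed = 1, p = 0.5) {
  set.seed(seed)
  samples <- sprintf("s%02d", seq_len(n))
  loci <- sprintf("L%02d", seq_len(L))
  mk <- function(enzyme) {
    toy_matrix(matrix(rbinom(n * L, 1, p), n, L), enzyme, samples, loci)
  }
  pm <- toy_popmap(samples, rep_len(paste0("P", seq_len(n_pops)), n))
  msap_dataset(mk("HPA"), mk("MSP"), pm)
}

# Brute-force AMOVA oracle: explicit double loops over the spec formulas,
# independent of the package implementation.
amova_oracle <- function(D2, pop) {
  n <- nrow(D2)
  ss_t <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_t <- ss_t + D2[i, j]
  ss_t <- ss_t / n
  groups <- unique(pop)
  ss_w <- 0
  for (g in groups) {
    idx <- which(pop == g)
    ng <- length(idx)
    acc <- 0
    if (ng > 1) {
      for (a in seq_len(ng - 1)) for (b in (a + 1):ng) {
        acc <- acc + D2[idx[a], idx[b]]
      }
    }
    ss_w <- ss_w + acc / ng
  }
  G <- length(groups)
  n_g <- table(pop)
  sigma_w <- (ss_w) / (n - G)
  n0 <- (n - sum(n_g^2) / n) / (G - 1)
  sigma_a <- ((ss_t - ss_w) / (G - 1) - sigma_w) / n0
  list(ss_total = ss_t, ss_within = ss_w, ss_among = ss_t - ss_w,
       sigma2_a = sigma_a, sigma2_w = sigma_w,
       phi_st = sigma_a / (sigma_a + sigma_w))
}

# planted K-class binary mixture: presence probabilities p_hi / p_lo
planted_mixture <- function(n_per, L, p_hi = 0.95, p_lo = 0.05, K = 2,
                            seed = 1) {
  set.seed(seed)
  blocks <- lapply(seq_len(K), function(k) {
    p <- rep(p_lo, L)
    idx <- ((k - 1) * floor(L / K) + 1):(k * floor(L / K))
    p[idx] <- p_hi
    matrix(rbinom(n_per * L, 1, rep(p, each = n_per)), n_per, L)
  })
  m <- do.call(rbind, blocks)
  dimnames(m) <- list(sprintf("s%03d", seq_len(nrow(m))),
                      sprintf("L%03d", seq_len(L)))
  list(x = band_matrix(m, "MSP"), truth = rep(seq_len(K), each = n_per))
}

# agreement of a hard partition with truth, maximised over label permutations
partition_agreement <- function(assign, truth) {
  K <- max(truth)
  best <- 0
  for (p in combinat_perms(K)) best <- max(best, mean(p[assign] == truth))
  best
}

combinat_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(k - 1)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
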