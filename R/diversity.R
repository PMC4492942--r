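#' Per-population band statistics
#'
#' The dominant-marker summary columns of an AFLP/MSAP diversity table, per
#' population: number of bands present, number of bands at within-population
#' frequency above `freq_threshold`, private bands (absent from every other
#' population), locally common bands, and mean expected heterozygosity with
#' its standard error over loci.
#'
#' A band is *locally common* at population fraction `f` for a population
#' when it is present there, its overall frequency exceeds `freq_threshold`,
#' and it occurs in at most `f` of all populations (the GenAlEx convention:
#' "found in 25% / 50% or fewer populations"). With a single population the
#' locally-common columns are undefined and returned as `NA` with a warning.
#'
#' @param x a [band_matrix()].
#' @param popmap a [popmap()].
#' @param freq_threshold band-frequency cutoff, strict inequality (default
#'   0.05, i.e. "frequency > 5%").
#' @param common_pop_fractions population fractions for the locally-common
#'   columns (default `c(0.25, 0.5)`).
#' @param estimator heterozygosity estimator, see
#'   [expected_heterozygosity()].
#' @return Data frame, one row per population, columns `population`, `n`,
#'   `n_bands`, `n_bands_freq`, `n_private_bands`, `n_common_25`,
#'   `n_common_50` (names follow `common_pop_fractions`), `mean_he`,
#'   `sem_he`.
#' @export
population_band_stats <- function(x, popmap, freq_threshold = 0.05,
                                  common_pop_fractions = c(0.25, 0.5),
                                  estimator = "hw_sqrt") {
  stopifnot(inherits(x, "band_matrix"))
  pf <- band_frequency(x, popmap)          # population x locus frequencies
  pops <- rownames(pf)
  G <- length(pops)
  present <- pf > 0                        # population x locus presence
  overall <- band_frequency(x)
  n_pops_with_band <- colSums(present, na.rm = TRUE)
  single_pop <- G < 2
  if (single_pop) {
    warning("single population: private/locally-common columns undefined")
  }
  common_cols <- lapply(common_pop_fractions, function(f) {
    if (single_pop) return(rep(NA_integer_, G))
    sapply(pops, function(p) {
      sum(present[p, ] & overall > freq_threshold &
            n_pops_with_band <= f * G)
    })
  })
  names(common_cols) <- paste0("n_common_", round(100 * common_pop_fractions))
  rows <- lapply(seq_along(pops), function(i) {
    p <- pops[i]
    ids <- popmap$sample[popmap$population == p]
    he <- expected_heterozygosity(pf[p, ], estimator = estimator)
    data.frame(
      population = p,
      n = length(intersect(ids, rownames(x))),
      n_bands = sum(present[p, ]),
      n_bands_freq = sum(pf[p, ] > freq_threshold),
      n_private_bands = if (single_pop) NA_integer_ else
        sum(present[p, ] & n_pops_with_band == 1L),
      mean_he = he$mean,
      sem_he = he$sem,
      row.names = NULL
    )
  })
  out <- do.call(rbind, rows)
  for (nm in names(common_cols)) out[[nm]] <- common_cols[[nm]]
  out[, c("population", "n", "n_bands", "n_bands_freq", "n_private_bands",
          names(common_cols), "mean_he", "sem_he")]
}

#' Expected heterozygosity from dominant-marker band frequencies
#'
#' For a dominant binary marker with band frequency `f`, the default
#' `"hw_sqrt"` estimator infers the null-allele frequency under
#' Hardy-Weinberg as `q = sqrt(1 - f)` and reports `He = 2 p q` with
#' `p = 1 - q`. The `"phenotypic"` estimator treats the band itself as the
#' allele: `He = 2 f (1 - f)`. Both vanish iff `f` is 0 or 1 and are bounded
#' by 0.5.
#'
#' @param freqs per-locus band frequencies in \[0,1\].
#' @param estimator `"hw_sqrt"` (default) or `"phenotypic"`.
#' @return List with `per_locus`, `mean`, and `sem` (sd of per-locus He over
#'   sqrt of the number of loci).
#' @export
expected_heterozygosity <- function(freqs, estimator = c("hw_sqrt", "phenotypic")) {
  estimator <- match.arg(estimator)
  stopifnot(all(freqs >= 0 & freqs <= 1))
  he <- switch(estimator,
    hw_sqrt = {
      q <- sqrt(1 - freqs)
      2 * (1 - q) * q
    },
    phenotypic = 2 * freqs * (1 - freqs)
  )
  n <- length(he)
  list(per_locus = he, mean = mean(he),
       sem = if (n > 1) stats::sd(he) / sqrt(n) else 0)
}

#' Shannon diversity index over band frequencies
#'
#' Per locus with presence frequency `f`, the entropy
#' `S = -(f log f + (1 - f) log(1 - f))` (with `0 log 0 = 0`); the index `I`
#' is the mean of `S` over the chosen locus set. Natural logarithm by
#' default.
#'
#' @param x a [band_matrix()].
#' @param loci optional character vector restricting the locus set (e.g. the
#'   MSL subset from [partition_loci()]).
#' @param base logarithm base (default `exp(1)`).
#' @return List of class `"shannon_result"` with `per_locus`, `index`,
#'   `n_loci`, `base`.
#' @export
shannon_index <- function(x, loci = NULL, base = exp(1)) {
  stopifnot(inherits(x, "band_matrix"), nrow(x) >= 2)
  f <- band_frequency(x)
  if (!is.null(loci)) {
    missing <- setdiff(loci, names(f))
    if (length(missing)) stop("unknown loci: ", paste(missing, collapse = ", "))
    f <- f[loci]
  }
  if (length(f) == 0L) stop("empty locus set")
  term <- function(p) ifelse(p > 0, -p * log(p, base = base), 0)
  s <- term(f) + term(1 - f)
  structure(list(per_locus = s, index = mean(s), n_loci = length(s),
                 base = base),
            class = "shannon_result")
}

#' @export
print.shannon_result <- function(x, ...) {
  cat(sprintf("Shannon diversity index I = %.4f over %d loci\n",
              x$index, x$n_loci))
  invisible(x)
}

#' Wilcoxon rank-sum test (two samples)
#'
#' Midrank ties; exact enumeration when the pooled size is at most 12 and
#' there are no ties, otherwise the normal approximation with continuity
#' correction. Degenerate input (all pooled values identical) returns p = 1
#' with a warning.
#'
#' @param x,y numeric vectors.
#' @param continuity use the continuity correction in the normal
#'   approximation (default `TRUE`).
#' @return `htest` object from [stats::wilcox.test()].
#' @export
wilcoxon_rank_sum <- function(x, y, continuity = TRUE) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical; p = 1")
    res <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = continuity))
    res$p.value <- 1
    return(res)
  }
  ties <- any(duplicated(pooled))
  exact <- (length(pooled) <= 12L) && !ties
  stats::wilcox.test(x, y, exact = exact, correct = continuity)
}

#' Kruskal-Wallis H test over two or more groups
#'
#' Tie-corrected H statistic with a chi-square approximation on
#' `length(groups) - 1` degrees of freedom.
#'
#' @param groups list of two or more nonempty numeric vectors.
#' @return `htest` object from [stats::kruskal.test()].
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least two groups")
  }
  if (any(lengths(groups) == 0L)) stop("empty group")
  stats::kruskal.test(groups)
}
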