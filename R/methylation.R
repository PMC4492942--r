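# Isoschizomer truth table. HpaII and MspI share the CCGG target but are
# blocked by different cytosine-methylation configurations, so the joint
# presence/absence pattern of a fragment across the two digests encodes the
# methylation state of the site:
#   HpaII 1 / MspI 1 -> hemi-methylation of the inner cytosine     (I)
#   HpaII 1 / MspI 0 -> hemi-methylation of the outer cytosine     (O)
#   HpaII 0 / MspI 1 -> double-strand methylation of inner cytosine (D)
#   HpaII 0 / MspI 0 -> double-strand methylation of inner and outer
#                       cytosine, or absence of the target          (U)
# Note this follows the source study's reading of the 1/1 pattern; much of
# the MSAP literature (e.g. the msap package) labels 1/1 "unmethylated".
# The `nomenclature` flag relabels outputs without changing any computation.

STATE_CODES <- c("I", "O", "D", "U")

STATE_LABELS <- c(
  I = "hemi-methylation of inner cytosine",
  O = "hemi-methylation of outer cytosine",
  D = "double-strand methylation of inner cytosine",
  U = "double-strand methylation of inner and outer cytosine or absence of target"
)

STATE_LABELS_MSAP <- c(
  I = "unmethylated (msap nomenclature)",
  O = "CNG hemi-methylation (msap nomenclature)",
  D = "CG methylation (msap nomenclature)",
  U = "fully methylated or absent (msap nomenclature)"
)

#' Classify a joint HpaII/MspI band pattern
#'
#' Vectorised total map from \{0,1\}^2 to the four methylation states,
#' returned as single-letter codes: `"I"` (1/1), `"O"` (1/0), `"D"` (0/1),
#' `"U"` (0/0). See [state_legend()] for the full labels.
#'
#' @param hpa,msp equal-length vectors of 0/1 band scores.
#' @return Character vector of state codes.
#' @export
classify_pattern <- function(hpa, msp) {
  if (length(hpa) != length(msp)) stop("hpa and msp lengths differ")
  if (!all(hpa %in% c(0, 1)) || !all(msp %in% c(0, 1))) {
    stop("band scores must be 0 or 1")
  }
  # index 1..4 over (hpa, msp) = (1,1), (1,0), (0,1), (0,0)
  idx <- 1L + (1L - as.integer(msp)) + 2L * (1L - as.integer(hpa))
  STATE_CODES[idx]
}

#' Decode state codes back to band bits
#'
#' Inverse of [classify_pattern()]; `decode_state(classify_pattern(h, m))`
#' reproduces `h` and `m` exactly.
#'
#' @param state character vector of codes in `c("I","O","D","U")`.
#' @return List with integer vectors `hpa` and `msp`.
#' @export
decode_state <- function(state) {
  i <- match(state, STATE_CODES)
  if (anyNA(i)) stop("unknown state code(s): ",
                     paste(unique(state[is.na(i)]), collapse = ", "))
  list(hpa = as.integer(i <= 2L), msp = as.integer(i %% 2L == 1L))
}

#' State legend
#'
#' @param nomenclature `"table1"` (the source study's labels) or `"msap"`
#'   (the convention of the msap package, where 1/1 is "unmethylated").
#' @return Named character vector mapping codes to labels.
#' @export
state_legend <- function(nomenclature = c("table1", "msap")) {
  switch(match.arg(nomenclature), table1 = STATE_LABELS, msap = STATE_LABELS_MSAP)
}

#' Classify every cell of an MSAP dataset
#'
#' @param ds an [msap_dataset()].
#' @return A sample x locus character matrix of state codes, class
#'   `"methylation_states"`.
#' @export
classify_dataset <- function(ds) {
  stopifnot(inherits(ds, "msap_dataset"))
  st <- classify_pattern(as.vector(unclass(ds$hpa)), as.vector(unclass(ds$msp)))
  m <- matrix(st, nrow(ds$hpa), ncol(ds$hpa), dimnames = dimnames(ds$hpa))
  structure(m, class = c("methylation_states", "matrix", "array"))
}

#' @export
print.methylation_states <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = STATE_CODES))
  cat(sprintf("Methylation state matrix: %d samples x %d loci\n", nrow(x), ncol(x)))
  print(round(tab / sum(tab), 3))
  invisible(x)
}

#' Partition loci into methylation-susceptible (MSL) and non-methylated (NML)
#' sets and flag polymorphic loci
#'
#' A locus shows methylation evidence in a sample when its state is `"O"`
#' (hemi-methylation of the outer cytosine) or `"D"` (double-strand
#' methylation of the inner cytosine) — the two patterns that can only arise
#' through differential isoschizomer blocking. A locus is MSL when the
#' fraction of samples with such evidence is at least `msl_threshold`
#' (default: any single sample, i.e. 1/n). A locus is polymorphic when its
#' most frequent joint pattern has frequency at most
#' `1 - polymorphism_threshold`; the 5% boundary is inclusive, so a minor
#' pattern at exactly 5% counts as polymorphism.
#'
#' @param states a [classify_dataset()] result.
#' @param msl_threshold fraction in \[0,1\]; `NULL` means one sample's worth.
#' @param polymorphism_threshold minor-pattern frequency cutoff (default 0.05).
#' @return Data frame (one row per locus) with columns `locus`, `is_msl`,
#'   `is_polymorphic`, `methylation_evidence_fraction`, `major_pattern_freq`.
#' @export
partition_loci <- function(states, msl_threshold = NULL,
                           polymorphism_threshold = 0.05) {
  stopifnot(inherits(states, "methylation_states"))
  n <- nrow(states)
  if (is.null(msl_threshold)) msl_threshold <- 1 / n
  stopifnot(msl_threshold >= 0, msl_threshold <= 1,
            polymorphism_threshold >= 0, polymorphism_threshold <= 1)
  ev <- colMeans(unclass(states) == "O" | unclass(states) == "D")
  major <- apply(unclass(states), 2, function(col) {
    max(tabulate(match(col, STATE_CODES), nbins = 4L)) / length(col)
  })
  data.frame(
    locus = colnames(states),
    is_msl = ev >= msl_threshold,
    is_polymorphic = major <= 1 - polymorphism_threshold,
    methylation_evidence_fraction = ev,
    major_pattern_freq = major,
    row.names = NULL
  )
}

#' Fraction of polymorphic loci
#'
#' @param classification a [partition_loci()] result.
#' @param restrict_to `"all"`, `"msl"` or `"nml"`.
#' @return Fraction in \[0,1\]; `NA` with a warning when the restriction set
#'   is empty.
#' @export
polymorphism_rate <- function(classification, restrict_to = c("all", "msl", "nml")) {
  restrict_to <- match.arg(restrict_to)
  keep <- switch(restrict_to,
                 all = rep(TRUE, nrow(classification)),
                 msl = classification$is_msl,
                 nml = !classification$is_msl)
  if (!any(keep)) {
    warning("no loci in restriction set '", restrict_to, "'; rate undefined")
    return(NA_real_)
  }
  mean(classification$is_polymorphic[keep])
}

#' Per-group methylation-level report
#'
#' For each group of samples, the proportion of sample x locus cells in each
#' of the four methylation states (rows of the report sum to 1). With
#' `include_uninformative = FALSE` the `"U"` (fully-methylated-or-absent)
#' cells are removed from the denominator, since they cannot be told apart
#' from missing targets.
#'
#' @param states a [classify_dataset()] result.
#' @param groups named character vector or factor: sample id -> group label.
#' @param include_uninformative keep `"U"` cells in the denominator (default).
#' @return Data frame with columns `group`, `n_cells`, `I`, `O`, `D`, `U`.
#' @export
methylation_level_report <- function(states, groups, include_uninformative = TRUE) {
  stopifnot(inherits(states, "methylation_states"))
  g <- groups[rownames(states)]
  if (anyNA(g)) {
    stop("ungrouped samples: ",
         paste(rownames(states)[is.na(g)], collapse = ", "))
  }
  out <- lapply(unique(g), function(grp) {
    cells <- unclass(states)[g == grp, , drop = FALSE]
    counts <- tabulate(match(cells, STATE_CODES), nbins = 4L)
    names(counts) <- STATE_CODES
    if (!include_uninformative) counts["U"] <- 0
    tot <- sum(counts)
    if (tot == 0) {
      warning("group '", grp, "' has no informative cells")
      props <- rep(NA_real_, 4)
    } else {
      props <- counts / tot
    }
    data.frame(group = grp, n_cells = tot, I = props[1], O = props[2],
               D = props[3], U = props[4], row.names = NULL)
  })
  do.call(rbind, out)
}

#' Per-sample relative methylation levels
#'
#' Fractions of each sample's loci in each category, for downstream rank
#' tests: `hemi_inner` (state I), `cng` (state O, CNG-methylation evidence
#' under the msap convention), `cg` (state D, CG-methylation evidence),
#' `full_or_absent` (state U), plus the inclusive `methylated_total`
#' (O + D + U) and `non_methylated` (= I) contrasts.
#'
#' @param states a [classify_dataset()] result.
#' @return Data frame with one row per sample.
#' @export
relative_methylation_series <- function(states) {
  stopifnot(inherits(states, "methylation_states"))
  m <- unclass(states)
  frac <- function(code) rowMeans(m == code)
  data.frame(
    sample = rownames(m),
    hemi_inner = frac("I"),
    cng = frac("O"),
    cg = frac("D"),
    full_or_absent = frac("U"),
    methylated_total = frac("O") + frac("D") + frac("U"),
    non_methylated = frac("I"),
    row.names = NULL
  )
}

#' Write a state matrix as CSV with a sidecar legend
#'
#' @param states a [classify_dataset()] result.
#' @param path CSV output path; the legend goes to `<path>.legend.json`.
#' @param nomenclature passed to [state_legend()].
#' @return `path`, invisibly.
#' @export
write_state_matrix <- function(states, path, nomenclature = "table1") {
  df <- data.frame(sample = rownames(states), unclass(states),
                   check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  jsonlite::write_json(as.list(state_legend(nomenclature)),
                       paste0(path, ".legend.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
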