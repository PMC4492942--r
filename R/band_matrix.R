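#' Construct a binary band matrix
#'
#' A band matrix holds presence/absence (1/0) scores of anonymous MSAP
#' fragments for one enzyme combination (EcoRI-HpaII or EcoRI-MspI): rows are
#' samples, columns are loci (conventionally named by primer-combination tag
#' plus fragment size in bp).
#'
#' @param x numeric or integer matrix of 0/1 values with sample ids as row
#'   names and locus ids as column names.
#' @param enzyme one of `"HPA"` (EcoRI-HpaII) or `"MSP"` (EcoRI-MspI).
#' @return An integer matrix of class `"band_matrix"` with attribute
#'   `enzyme`.
#' @export
band_matrix <- function(x, enzyme = c("HPA", "MSP")) {
  enzyme <- match.arg(enzyme)
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("band matrix requires sample ids as row names and locus ids as column names")
  }
  storage.mode(x) <- "integer"
  validate_band_matrix(x)
  structure(x, enzyme = enzyme, class = c("band_matrix", "matrix", "array"))
}

validate_band_matrix <- function(x) {
  if (anyDuplicated(rownames(x))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate locus ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  }
  if (anyNA(x)) stop("band matrix contains missing values")
  if (!all(x %in% c(0L, 1L))) {
    bad <- unique(x[!(x %in% c(0L, 1L))])
    stop("band matrix entries must be 0 or 1; found: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(x)
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("MSAP band matrix (%s): %d samples x %d loci, %d bands present\n",
              attr(x, "enzyme"), nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Read a band matrix from tabular text
#'
#' Expects a header row of locus ids and a first column of sample ids.
#' Delimiter is comma for `.csv` and tab for `.tsv`/`.txt` unless `sep` is
#' given. Cells must be 0 or 1; under the default strict policy anything else
#' (including missing cells) is an error, while `missing = "drop_locus"`
#' silently removes any locus column containing a missing value and records
#' the dropped ids in attribute `dropped_loci`.
#'
#' @param path file path.
#' @param enzyme `"HPA"` or `"MSP"`.
#' @param missing `"error"` (default) or `"drop_locus"`.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return A [band_matrix()].
#' @export
read_band_matrix <- function(path, enzyme = c("HPA", "MSP"),
                             missing = c("error", "drop_locus"), sep = NULL) {
  enzyme <- match.arg(enzyme)
  missing <- match.arg(missing)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("malformed band matrix file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(tab) == 0L || ncol(tab) == 0L) {
    stop("band matrix file '", path, "' has no data")
  }
  m <- as.matrix(tab)
  suppressWarnings(storage.mode(m) <- "integer")
  dropped <- character()
  if (anyNA(m)) {
    if (missing == "error") {
      stop("band matrix '", path, "' contains missing or non-numeric cells")
    }
    keep <- !apply(is.na(m), 2, any)
    dropped <- colnames(m)[!keep]
    m <- m[, keep, drop = FALSE]
    if (ncol(m) == 0L) stop("all loci dropped by missing-value policy")
  }
  out <- band_matrix(m, enzyme)
  attr(out, "dropped_loci") <- dropped
  out
}

#' Write a band matrix as tabular text
#'
#' @param x a [band_matrix()].
#' @param path output path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(x, path, sep = ",") {
  df <- data.frame(sample = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a population map
#'
#' Tabular text with columns `sample`, `population` and optionally `lat`,
#' `lon`, `genotype`. Each sample must appear exactly once; coordinates, when
#' present, must satisfy |lat| <= 90 and |lon| <= 180.
#'
#' @param path file path.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return A data frame of class `"popmap"`.
#' @export
read_popmap <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  popmap(df)
}

#' Construct/validate a population map
#'
#' @param df data frame with columns `sample`, `population` and optionally
#'   `lat`, `lon`, `genotype`.
#' @return `df` with class `"popmap"` prepended.
#' @export
popmap <- function(df) {
  need <- c("sample", "population")
  if (!all(need %in% names(df))) {
    stop("population map needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$sample)) {
    stop("samples mapped to more than one population: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  }
  if (anyNA(df$population)) stop("missing population assignment")
  if (all(c("lat", "lon") %in% names(df))) {
    ok <- is.na(df$lat) | (abs(df$lat) <= 90 & abs(df$lon) <= 180)
    if (!all(ok)) {
      stop("invalid coordinates for: ", paste(df$sample[!ok], collapse = ", "))
    }
  }
  df$sample <- as.character(df$sample)
  df$population <- as.character(df$population)
  class(df) <- unique(c("popmap", class(df)))
  df
}

#' Pair the HpaII and MspI band matrices into one MSAP dataset
#'
#' Aligns the two matrices and the population map on a canonical
#' (lexicographic) sample and locus order, so downstream results are
#' reproducible across input shufflings. Sample sets must match exactly.
#' Locus sets must match exactly under the default `loci = "strict"`;
#' `loci = "intersect"` instead keeps the shared loci and warns, listing the
#' discarded ids.
#'
#' @param hpa,msp [band_matrix()] objects with enzymes `"HPA"` and `"MSP"`.
#' @param popmap a [popmap()] covering every sample.
#' @param loci `"strict"` or `"intersect"`.
#' @return A list of class `"msap_dataset"` with elements `hpa`, `msp`,
#'   `popmap`.
#' @export
msap_dataset <- function(hpa, msp, popmap, loci = c("strict", "intersect")) {
  loci <- match.arg(loci)
  stopifnot(inherits(hpa, "band_matrix"), inherits(msp, "band_matrix"))
  if (!identical(attr(hpa, "enzyme"), "HPA") ||
      !identical(attr(msp, "enzyme"), "MSP")) {
    stop("expected enzymes HPA and MSP, in that order")
  }
  only_h <- setdiff(rownames(hpa), rownames(msp))
  only_m <- setdiff(rownames(msp), rownames(hpa))
  if (length(only_h) || length(only_m)) {
    stop("sample sets differ between enzyme matrices; HPA-only: {",
         paste(only_h, collapse = ", "), "}, MSP-only: {",
         paste(only_m, collapse = ", "), "}")
  }
  lh <- colnames(hpa); lm <- colnames(msp)
  shared <- intersect(lh, lm)
  if (!setequal(lh, lm)) {
    if (loci == "strict") {
      stop("locus sets differ between enzyme matrices; HPA-only: {",
           paste(setdiff(lh, lm), collapse = ", "), "}, MSP-only: {",
           paste(setdiff(lm, lh), collapse = ", "),
           "} (use loci = \"intersect\" to keep the ", length(shared),
           " shared loci)")
    }
    warning("dropping unshared loci: ",
            paste(sort(union(setdiff(lh, lm), setdiff(lm, lh))), collapse = ", "))
  }
  samp <- sort(rownames(hpa))
  loc <- sort(shared)
  missing_pop <- setdiff(samp, popmap$sample)
  if (length(missing_pop)) {
    stop("samples absent from population map: ",
         paste(missing_pop, collapse = ", "))
  }
  pm <- popmap[match(samp, popmap$sample), , drop = FALSE]
  rownames(pm) <- NULL
  out <- list(
    hpa = band_matrix(unclass(hpa)[samp, loc, drop = FALSE], "HPA"),
    msp = band_matrix(unclass(msp)[samp, loc, drop = FALSE], "MSP"),
    popmap = pm
  )
  class(out) <- "msap_dataset"
  out
}

#' @export
print.msap_dataset <- function(x, ...) {
  cat(sprintf(
    "MSAP dataset: %d samples, %d loci, %d populations\n",
    nrow(x$hpa), ncol(x$hpa), length(unique(x$popmap$population))))
  invisible(x)
}

#' Per-locus band frequencies
#'
#' Fraction of samples carrying each band, overall or within each population.
#' An empty population yields a row of `NA` with a warning rather than silent
#' zeros.
#'
#' @param x a [band_matrix()].
#' @param popmap optional [popmap()]; when given, one row per population.
#' @return Named numeric vector (overall) or a population x locus matrix.
#' @export
band_frequency <- function(x, popmap = NULL) {
  stopifnot(inherits(x, "band_matrix"), nrow(x) >= 1)
  if (is.null(popmap)) {
    return(colMeans(unclass(x)))
  }
  pops <- unique(popmap$population)
  out <- matrix(NA_real_, length(pops), ncol(x),
                dimnames = list(pops, colnames(x)))
  for (p in pops) {
    ids <- popmap$sample[popmap$population == p]
    ids <- intersect(ids, rownames(x))
    if (length(ids) == 0L) {
      warning("population '", p, "' has no samples in the matrix; frequencies undefined")
      next
    }
    out[p, ] <- colMeans(unclass(x)[ids, , drop = FALSE])
  }
  out
}
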