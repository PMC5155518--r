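#' Genotype matrices for association mapping
#'
#' A genotype matrix holds the per-individual predictor values used by the
#' scans: coded SNP calls for QTS mapping (`+1` for one homozygote, `-1` for
#' the other, `0` for heterozygotes) or continuous omics abundances
#' (transcript/protein/metabolite levels) for QTT/P/M mapping.
#'
#' @param values numeric matrix, individuals in rows (rownames = individual
#'   ids), markers in columns (colnames = marker ids).
#' @param mode `"categorical_homozygote"` (coded SNPs) or `"continuous"`.
#' @param standardize for continuous mode, center and scale each column to
#'   unit variance so effect sizes and heritabilities are on the same scale
#'   as the coded-SNP case. Default `TRUE`; set `FALSE` to keep the raw
#'   scale.
#' @return An object of class `qtx_geno`: a list with elements `values`
#'   (numeric matrix), `mode`, `monomorphic` (logical per marker) and
#'   `coding` (symbol map, for coded matrices).
#' @seealso [code_genotypes()] to build one from raw symbolic calls.
#' @export
genotype_matrix <- function(values,
                            mode = c("categorical_homozygote", "continuous"),
                            standardize = TRUE) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- paste0("ind", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("m", seq_len(ncol(values)))
  if (anyDuplicated(colnames(values)))
    stop("duplicated marker ids in genotype matrix")
  if (anyDuplicated(rownames(values)))
    stop("duplicated individual ids in genotype matrix")
  if (mode == "categorical_homozygote") {
    bad <- !(values %in% c(-1, 0, 1) | is.na(values))
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("categorical genotype value not in {-1, 0, +1} at [%s, %s]",
                   rownames(values)[(i - 1L) %% nrow(values) + 1L],
                   colnames(values)[(i - 1L) %/% nrow(values) + 1L]))
    }
  } else {
    if (any(!is.finite(values) & !is.na(values)))
      stop("continuous genotype values must be finite")
    if (standardize) {
      mu <- colMeans(values, na.rm = TRUE)
      sd <- apply(values, 2L, stats::sd, na.rm = TRUE)
      sd[sd == 0 | is.na(sd)] <- 1
      values <- sweep(sweep(values, 2L, mu), 2L, sd, "/")
    }
  }
  mono <- apply(values, 2L, function(x) {
    x <- x[!is.na(x)]
    length(x) == 0L || all(x == x[1L])
  })
  structure(list(values = values, mode = mode, monomorphic = mono,
                 coding = NULL),
            class = "qtx_geno")
}

#' Code raw genotype calls to the +1/-1/0 convention
#'
#' Maps symbolic homozygote/heterozygote calls onto the numeric coding used
#' by the mixed model: `+1` for one homozygote class, `-1` for the other,
#' `0` for heterozygotes. Designed for homozygous mapping populations
#' (RILs, DH lines), where heterozygotes are rare residual calls.
#'
#' @param raw character matrix of calls (individuals x markers).
#' @param alleles named character vector declaring the alphabet:
#'   `c(plus = , minus = , het = , missing = )`.
#' @param missing how to handle missing calls: `"mean"` (default) imputes
#'   the marker's mean coded value; `"keep"` leaves `NA` (rows are then
#'   dropped per test by the projector-based test functions).
#' @return A `qtx_geno` in categorical mode, with the symbol-to-code map in
#'   `$coding` and monomorphic markers flagged in `$monomorphic`.
#' @examples
#' raw <- matrix(c("QQ", "qq", "Qq", "QQ"), 2, 2,
#'               dimnames = list(c("i1", "i2"), c("m1", "m2")))
#' code_genotypes(raw)$values
#' @export
code_genotypes <- function(raw,
                           alleles = c(plus = "QQ", minus = "qq",
                                       het = "Qq", missing = "--"),
                           missing = c("mean", "keep")) {
  missing <- match.arg(missing)
  raw <- as.matrix(raw)
  need <- c("plus", "minus", "het", "missing")
  if (!all(need %in% names(alleles)))
    stop("`alleles` must name plus, minus, het and missing symbols")
  code <- c(1, -1, 0, NA_real_)
  names(code) <- alleles[need]
  known <- raw %in% names(code)
  if (!all(known)) {
    i <- which(!known)[1L]
    r <- (i - 1L) %% nrow(raw) + 1L
    c <- (i - 1L) %/% nrow(raw) + 1L
    stop(sprintf("unknown genotype symbol '%s' at [%s, %s]",
                 raw[i],
                 rownames(raw)[r] %||% r, colnames(raw)[c] %||% c))
  }
  vals <- matrix(code[raw], nrow(raw), ncol(raw), dimnames = dimnames(raw))
  if (is.null(rownames(vals))) rownames(vals) <- paste0("ind", seq_len(nrow(vals)))
  if (is.null(colnames(vals))) colnames(vals) <- paste0("m", seq_len(ncol(vals)))
  imputed <- FALSE
  if (missing == "mean" && anyNA(vals)) {
    imputed <- TRUE
    for (j in seq_len(ncol(vals))) {
      na <- is.na(vals[, j])
      if (any(na)) vals[na, j] <- mean(vals[, j], na.rm = TRUE)
    }
    vals[is.nan(vals)] <- 0  # marker entirely missing
  }
  mono <- apply(vals, 2L, function(x) {
    x <- x[!is.na(x)]
    length(x) == 0L || all(x == x[1L])
  })
  # mean imputation can introduce fractional codes, so the object is built
  # directly rather than through the strict categorical validator
  structure(list(values = vals, mode = "categorical_homozygote",
                 monomorphic = mono,
                 coding = c(stats::setNames(as.list(code), names(code)),
                            list(imputed = imputed))),
            class = "qtx_geno")
}

#' Epistasis coefficient of a pair of loci
#'
#' Product coding for additive-by-additive epistasis: the pair coefficient
#' is `x_i * x_j`. For coded homozygotes this reproduces the +1 for like
#' pairs (`QQ x QQ`, `qq x qq`) and -1 for unlike pairs (`QQ x qq`,
#' `qq x QQ`) rule, and extends unchanged to continuous predictors.
#'
#' @param x_i,x_j numeric coefficients (vectors recycle as in `*`).
#' @return `x_i * x_j`.
#' @export
epistasis_coefficient <- function(x_i, x_j) x_i * x_j

#' @export
print.qtx_geno <- function(x, ...) {
  cat(sprintf("qtx_geno: %d individuals x %d markers (%s mode)%s\n",
              nrow(x$values), ncol(x$values), x$mode,
              if (any(x$monomorphic))
                sprintf(", %d monomorphic", sum(x$monomorphic)) else ""))
  invisible(x)
}

#' @export
as.matrix.qtx_geno <- function(x, ...) x$values

#' Restrict a genotype matrix (and map) to a thinned marker set
#'
#' Keeps every `step`-th marker plus any markers named in `keep` (causal
#' loci must survive thinning in power experiments). Markers stay in map
#' order.
#'
#' @param geno a `qtx_geno`.
#' @param map a `qtx_map` (see [genetic_map()]); optional.
#' @param step keep every `step`-th marker (in map/column order).
#' @param keep marker ids always retained.
#' @return list with elements `geno` and `map` (map `NULL` if not given).
#' @export
thin_markers <- function(geno, map = NULL, step = 5L, keep = character()) {
  ids <- colnames(geno$values)
  ord <- if (!is.null(map)) intersect(map$marker, ids) else ids
  sel <- union(ord[seq(1L, length(ord), by = step)], intersect(keep, ord))
  sel <- ord[ord %in% sel]
  g <- geno
  g$values <- geno$values[, sel, drop = FALSE]
  g$monomorphic <- geno$monomorphic[sel]
  list(geno = g,
       map = if (!is.null(map)) map[match(sel, map$marker), , drop = FALSE]
       else NULL)
}
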