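#' Build the mixed-model design for a set of candidate loci and pairs
#'
#' Constructs the fixed block and the four random-effect coefficient blocks
#' of the mixed linear model
#' \deqn{y = Xb + \sum_v U_v e_v + \epsilon}
#' where the fixed block `X` holds the intercept and environment contrasts,
#' and the random blocks are, in fixed order:
#' \describe{
#'   \item{A}{one column per locus, entries `x_ik` (additive main effects)}
#'   \item{AA}{one column per pair, entries `x_ik * x_jk` (epistasis)}
#'   \item{AE}{one column per locus x environment; entry `x_ik` when the
#'     record is in that environment, 0 otherwise}
#'   \item{AAE}{one column per pair x environment, the masked product}
#' }
#' With a single environment the AE and AAE blocks are empty (no
#' environment interaction is definable). Kinship matrices default to the
#' identity for every block; a user-supplied list can replace them.
#'
#' @param geno a `qtx_geno`.
#' @param pheno a `qtx_pheno`; rows of all blocks align with its records.
#' @param loci character vector of marker ids (additive terms).
#' @param pairs 2-column character matrix (or list of length-2 vectors) of
#'   marker pairs; stored in canonical order (lower column index first).
#' @param kinship optional named list of kinship matrices per block
#'   (`A`, `AA`, `AE`, `AAE`); `NULL` means identity.
#' @return An object of class `qtx_design`: list with `X` (fixed block),
#'   `blocks` (named list of coefficient matrices, only non-empty classes),
#'   `terms` (per-block data frames describing each column), `y`,
#'   `env`, `env_levels`, `individuals`, `kinship`.
#' @export
build_design <- function(geno, pheno, loci = character(),
                         pairs = NULL, kinship = NULL) {
  stopifnot(inherits(geno, "qtx_geno"))
  if (nrow(pheno) == 0L) stop("empty phenotype table")
  check_pheno_geno(pheno, geno)
  loci <- as.character(loci)
  if (anyDuplicated(loci))
    stop("locus listed twice: ", loci[duplicated(loci)][1L])
  ids <- colnames(geno$values)
  if (length(loci) && !all(loci %in% ids))
    stop("unknown locus: ", setdiff(loci, ids)[1L])
  pairs <- canonical_pairs(pairs, ids)

  lev <- env_levels(pheno)
  H <- length(lev)
  envf <- factor(pheno$environment, levels = lev)
  n <- nrow(pheno)
  ridx <- match(pheno$individual, rownames(geno$values))

  # fixed block: intercept + environment treatment contrasts
  X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  if (H > 1L) {
    E <- vapply(lev[-1L], function(h) as.numeric(envf == h), numeric(n))
    colnames(E) <- paste0("env:", lev[-1L])
    X <- cbind(X, E)
  }

  blocks <- list()
  terms <- list()

  if (length(loci)) {
    A <- geno$values[ridx, loci, drop = FALSE]
    dimnames(A) <- list(NULL, loci)
    blocks$A <- A
    terms$A <- data.frame(class = "A", locus1 = loci, locus2 = NA_character_,
                          environment = NA_character_,
                          stringsAsFactors = FALSE)
  }
  if (nrow(pairs)) {
    AA <- geno$values[ridx, pairs[, 1L], drop = FALSE] *
      geno$values[ridx, pairs[, 2L], drop = FALSE]
    colnames(AA) <- paste(pairs[, 1L], pairs[, 2L], sep = ":")
    blocks$AA <- AA
    terms$AA <- data.frame(class = "AA", locus1 = pairs[, 1L],
                           locus2 = pairs[, 2L],
                           environment = NA_character_,
                           stringsAsFactors = FALSE)
  }
  if (H > 1L) {
    mask <- vapply(lev, function(h) as.numeric(envf == h), numeric(n))
    if (length(loci)) {
      AE <- matrix(0, n, length(loci) * H)
      tl <- character(0); te <- character(0)
      k <- 0L
      for (i in seq_along(loci)) for (h in seq_len(H)) {
        k <- k + 1L
        AE[, k] <- blocks$A[, i] * mask[, h]
        tl[k] <- loci[i]; te[k] <- lev[h]
      }
      colnames(AE) <- paste0(tl, "@", te)
      blocks$AE <- AE
      terms$AE <- data.frame(class = "AE", locus1 = tl,
                             locus2 = NA_character_, environment = te,
                             stringsAsFactors = FALSE)
    }
    if (nrow(pairs)) {
      AAE <- matrix(0, n, nrow(pairs) * H)
      t1 <- character(0); t2 <- character(0); te <- character(0)
      k <- 0L
      for (i in seq_len(nrow(pairs))) for (h in seq_len(H)) {
        k <- k + 1L
        AAE[, k] <- blocks$AA[, i] * mask[, h]
        t1[k] <- pairs[i, 1L]; t2[k] <- pairs[i, 2L]; te[k] <- lev[h]
      }
      colnames(AAE) <- paste0(t1, ":", t2, "@", te)
      blocks$AAE <- AAE
      terms$AAE <- data.frame(class = "AAE", locus1 = t1, locus2 = t2,
                              environment = te, stringsAsFactors = FALSE)
    }
  }
  # fixed class order A, AA, AE, AAE
  ord <- intersect(c("A", "AA", "AE", "AAE"), names(blocks))
  blocks <- blocks[ord]
  terms <- terms[ord]

  if (!is.null(kinship)) {
    extra <- setdiff(names(kinship), names(blocks))
    if (length(extra)) stop("kinship given for absent block: ", extra[1L])
  }

  structure(list(X = X, blocks = blocks, terms = terms,
                 y = pheno$value, env = envf, env_levels = lev,
                 individuals = pheno$individual, kinship = kinship,
                 mode = geno$mode),
            class = "qtx_design")
}

# canonicalize a pair specification to a 2-column character matrix with the
# lower-column-index marker first, duplicates removed
canonical_pairs <- function(pairs, marker_ids) {
  if (is.null(pairs) || (is.matrix(pairs) && nrow(pairs) == 0L) ||
      length(pairs) == 0L)
    return(matrix(character(0), 0L, 2L))
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.character(pairs), ncol = 2L)
  bad <- !(pairs %in% marker_ids)
  if (any(bad)) stop("unknown marker in pair: ", pairs[bad][1L])
  if (any(pairs[, 1L] == pairs[, 2L]))
    stop("a pair must name two distinct loci")
  i1 <- match(pairs[, 1L], marker_ids)
  i2 <- match(pairs[, 2L], marker_ids)
  swap <- i1 > i2
  pairs[swap, ] <- pairs[swap, 2:1]
  pairs[!duplicated(paste(pairs[, 1L], pairs[, 2L])), , drop = FALSE]
}

#' @export
print.qtx_design <- function(x, ...) {
  w <- vapply(x$blocks, ncol, 0L)
  cat(sprintf("qtx_design: %d records, %d environments; fixed cols %d; random blocks: %s\n",
              length(x$y), length(x$env_levels), ncol(x$X),
              if (length(w)) paste(sprintf("%s(%d)", names(w), w),
                                   collapse = ", ") else "none"))
  invisible(x)
}

# subset a design's rows (used by the jackknife)
subset_design <- function(design, rows) {
  d <- design
  d$X <- design$X[rows, , drop = FALSE]
  d$blocks <- lapply(design$blocks, function(U) U[rows, , drop = FALSE])
  d$y <- design$y[rows]
  d$env <- design$env[rows]
  d$individuals <- design$individuals[rows]
  d
}
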