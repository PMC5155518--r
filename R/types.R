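#' Genetic map
#'
#' A genetic map locates markers on chromosomes in centimorgans (optionally
#' also base pairs). Marker ids must be unique and positions non-decreasing
#' within each chromosome.
#'
#' @param marker character marker ids.
#' @param chrom character chromosome ids.
#' @param cM numeric map positions (centimorgans, `>= 0`).
#' @param bp optional integer physical positions.
#' @return A data frame of class `qtx_map`.
#' @export
genetic_map <- function(marker, chrom, cM, bp = NULL) {
  map <- data.frame(marker = as.character(marker),
                    chrom = as.character(chrom),
                    cM = as.numeric(cM),
                    stringsAsFactors = FALSE)
  if (!is.null(bp)) map$bp <- as.integer(bp)
  if (anyDuplicated(map$marker))
    stop("duplicated marker id in map: ",
         map$marker[duplicated(map$marker)][1L])
  if (any(map$cM < 0)) stop("map positions must be >= 0 cM")
  for (ch in unique(map$chrom)) {
    pos <- map$cM[map$chrom == ch]
    if (is.unsorted(pos)) {
      bad <- map$marker[map$chrom == ch][which(diff(pos) < 0)[1L] + 1L]
      stop(sprintf("map positions not non-decreasing on chromosome %s (marker %s)",
                   ch, bad))
    }
  }
  class(map) <- c("qtx_map", "data.frame")
  map
}

#' Long-format phenotype table
#'
#' One record per observation: which individual, in which environment, with
#' what trait value. The same individual may be observed repeatedly in an
#' environment (replicated measurements).
#'
#' @param individual character individual ids.
#' @param environment environment labels (any atomic type; coerced to
#'   character).
#' @param value numeric trait values.
#' @return A data frame of class `qtx_pheno`.
#' @export
phenotype_table <- function(individual, environment, value) {
  if (length(individual) == 0L) stop("empty phenotype table")
  ph <- data.frame(individual = as.character(individual),
                   environment = as.character(environment),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  if (anyNA(ph$value)) stop("non-numeric or missing trait value in phenotype table")
  class(ph) <- c("qtx_pheno", "data.frame")
  ph
}

# sorted unique environment labels: the deterministic environment order
# used everywhere downstream
env_levels <- function(pheno) sort(unique(pheno$environment))

check_pheno_geno <- function(pheno, geno) {
  unknown <- setdiff(unique(pheno$individual), rownames(geno$values))
  if (length(unknown))
    stop("phenotype references individuals absent from genotypes: ",
         paste(unknown, collapse = ", "))
  invisible(TRUE)
}
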