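# TSV readers/writers and the end-to-end pipeline.
#
# All files are tab-delimited; lines starting with '#' are comments.
# Genotype TSV: header = marker ids, column 1 = individual id, cells =
# symbols or numeric codes/abundances. Map TSV: marker, chrom, cM[, bp].
# Phenotype TSV (long): individual, environment, value.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a genotype matrix from TSV
#'
#' Numeric cells are taken as coded/continuous predictors directly
#' (`mode` auto-detected: values inside \{-1, 0, +1\} mean coded SNPs);
#' non-numeric cells are passed through [code_genotypes()] with the given
#' alphabet.
#'
#' @param path TSV file; first column individual ids, remaining columns one
#'   marker each.
#' @param alleles symbol alphabet for symbolic input (see
#'   [code_genotypes()]).
#' @param missing missing-value handling for symbolic input.
#' @return a `qtx_geno`.
#' @export
read_genotypes <- function(path, alleles = c(plus = "QQ", minus = "qq",
                                             het = "Qq", missing = "--"),
                           missing = "mean") {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2L) stop("genotype file needs an id column plus markers: ", path)
  ids <- as.character(df[[1L]])
  mk <- names(df)[-1L]   # data.frame subsetting would uniquify duplicates
  if (anyDuplicated(mk))
    stop("duplicated marker in genotype header: ", mk[duplicated(mk)][1L])
  vals <- df[, -1L, drop = FALSE]
  colnames(vals) <- mk
  if (all(vapply(vals, is.numeric, TRUE))) {
    M <- as.matrix(vals)
    rownames(M) <- ids
    mode <- if (all(M %in% c(-1, 0, 1))) "categorical_homozygote" else "continuous"
    genotype_matrix(M, mode = mode, standardize = FALSE)
  } else {
    M <- as.matrix(vals)
    rownames(M) <- ids
    code_genotypes(M, alleles = alleles, missing = missing)
  }
}

#' Read a genetic map from TSV
#' @param path TSV with columns marker, chrom, cM and optionally bp.
#' @return a `qtx_map`; positions must be non-decreasing per chromosome.
#' @export
read_map <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("marker", "chrom", "cM")
  if (!all(need %in% colnames(df)))
    stop("map file must have columns marker, chrom, cM: ", path)
  genetic_map(df$marker, df$chrom, df$cM, df$bp)
}

#' Read a long-format phenotype table from TSV
#' @param path TSV with columns individual, environment, value.
#' @export
read_phenotypes <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("individual", "environment", "value")
  if (!all(need %in% colnames(df)))
    stop("phenotype file must have columns individual, environment, value: ",
         path)
  v <- suppressWarnings(as.numeric(df$value))
  if (anyNA(v)) {
    bad <- which(is.na(v))[1L]
    stop(sprintf("non-numeric trait value at data line %d of %s", bad, path))
  }
  phenotype_table(df$individual, df$environment, v)
}

# standard output header recording the run configuration
tsv_header <- function(seed = NA, alpha = NA, n_perm = NA) {
  c(sprintf("# qtxmap %s",
            as.character(utils::packageVersion("qtxmap"))),
    sprintf("# seed=%s alpha=%s n_perm=%s", seed, alpha, n_perm))
}

write_tsv_commented <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotype / map / phenotype TSVs
#'
#' Inverse of the readers; round-trips exactly for numeric matrices.
#' @param geno,map,pheno objects to write.
#' @param path output file.
#' @name write_inputs
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(individual = rownames(geno$values),
                   geno$values, check.names = FALSE)
  write_tsv_commented(df, path)
}

#' @rdname write_inputs
#' @export
write_map <- function(map, path) write_tsv_commented(as.data.frame(map), path)

#' @rdname write_inputs
#' @export
write_phenotypes <- function(pheno, path)
  write_tsv_commented(as.data.frame(pheno), path)

#' Run the full association-mapping pipeline
#'
#' Executes the four analysis steps in order -- 1D scan with permutation
#' threshold, 2D scan with its threshold, stepwise selection,
#' MINQUE(1)/AUP estimation, and Gibbs sampling of the final model -- and
#' writes all result TSVs plus a machine-readable JSON manifest to
#' `out_dir`. Re-running with the same inputs and seed reproduces every
#' output byte for byte. A failing stage aborts with the stage name;
#' outputs of completed stages are kept.
#'
#' @param geno,map,pheno input objects, or file paths understood by the
#'   readers.
#' @param out_dir output directory (created if needed).
#' @param alpha experiment-wise error rate.
#' @param n_perm permutations per threshold.
#' @param seed master seed for permutations and the Gibbs chain.
#' @param pair_scope 2D scan scope.
#' @param mcmc_length,mcmc_thin,mcmc_burn_in Gibbs chain settings.
#' @param run_mcmc set `FALSE` to stop after MINQUE/AUP.
#' @param se effect standard errors: `"none"` or `"jackknife"`.
#' @param jackknife_groups blocks for the grouped jackknife.
#' @return list with all intermediate objects (invisibly) and the manifest.
#' @export
run_pipeline <- function(geno, map = NULL, pheno, out_dir,
                         alpha = 0.05, n_perm = 2000L, seed = 1L,
                         pair_scope = c("selected", "all"),
                         mcmc_length = 200000L, mcmc_thin = 10L,
                         mcmc_burn_in = 20000L, run_mcmc = TRUE,
                         se = "none", jackknife_groups = NULL) {
  pair_scope <- match.arg(pair_scope)
  if (is.character(geno)) geno <- read_genotypes(geno)
  if (is.character(map)) map <- read_map(map)
  if (is.character(pheno)) pheno <- read_phenotypes(pheno)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- tsv_header(seed, alpha, n_perm)
  stages <- character(0)
  res <- list()
  stage <- function(name, code) {
    out <- tryCatch(code, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    stages <<- c(stages, name)
    out
  }

  res$scan1d <- stage("scan_1d", scan_1d(geno, pheno))
  res$threshold1d <- stage("permutation_threshold_1d",
                           permutation_threshold(geno, pheno, "1d",
                                                 alpha = alpha,
                                                 n_perm = n_perm,
                                                 seed = seed))
  s1 <- res$scan1d
  s1out <- data.frame(marker = s1$marker,
                      chrom = map$chrom[match(s1$marker, map$marker)] %||% NA,
                      cM = map$cM[match(s1$marker, map$marker)] %||% NA,
                      F = s1$F, p_point = s1$p_point,
                      significant = !s1$untestable &
                        s1$F >= res$threshold1d$critical_F)
  write_tsv_commented(s1out, file.path(out_dir, "scan1d.tsv"), hdr)

  sel <- find_peaks(res$scan1d, map, res$threshold1d$critical_F)
  res$selected <- sel
  if (length(sel) || pair_scope == "all") {
    res$scan2d <- stage("scan_2d",
                        scan_2d(geno, pheno, selected = sel,
                                scope = pair_scope))
    res$threshold2d <- stage("permutation_threshold_2d",
                             permutation_threshold(geno, pheno, "2d",
                                                   alpha = alpha,
                                                   n_perm = n_perm,
                                                   seed = seed,
                                                   selected = sel,
                                                   pair_scope = pair_scope))
    s2 <- res$scan2d
    s2out <- data.frame(marker_i = s2$marker_i, marker_j = s2$marker_j,
                        F = s2$F, p_point = s2$p_point,
                        significant = !s2$untestable &
                          s2$F >= res$threshold2d$critical_F)
    write_tsv_commented(s2out, file.path(out_dir, "scan2d.tsv"), hdr)
  }
  write_tsv_commented(
    data.frame(scope = c("1d", "2d"),
               critical_F = c(res$threshold1d$critical_F,
                              res$threshold2d$critical_F %||% NA),
               alpha = alpha, n_perm = n_perm),
    file.path(out_dir, "threshold.tsv"), hdr)

  res$candidates <- stage("stepwise_select",
                          stepwise_select(geno, pheno, res$scan1d,
                                          res$threshold1d, res$scan2d,
                                          res$threshold2d, map))
  cs <- res$candidates
  cand_tab <- rbind(
    data.frame(term = cs$loci$marker,
               type = rep("locus", nrow(cs$loci)),
               F_cond = cs$loci$F_cond, stringsAsFactors = FALSE),
    data.frame(term = paste(cs$pairs$marker_i, cs$pairs$marker_j, sep = ":"),
               type = rep("pair", nrow(cs$pairs)),
               F_cond = cs$pairs$F_cond, stringsAsFactors = FALSE))
  write_tsv_commented(cand_tab, file.path(out_dir, "candidates.tsv"), hdr)

  if (nrow(cs$loci) || nrow(cs$pairs)) {
    res$design <- build_design(geno, pheno, loci = cs$loci$marker,
                               pairs = as.matrix(cs$pairs[, 1:2]))
    res$vc <- stage("minque1", minque1(res$design))
    res$effects <- stage("aup_predict",
                         aup_predict(res$design, vc = res$vc, se = se,
                                     jackknife_groups = jackknife_groups))
    write_tsv_commented(
      data.frame(class = names(res$vc$sigma2), sigma2 = res$vc$sigma2,
                 h2 = res$vc$heritability),
      file.path(out_dir, "variance_components.tsv"), hdr)
    write_tsv_commented(as.data.frame(res$effects),
                        file.path(out_dir, "effects.tsv"), hdr)
    if (run_mcmc) {
      res$posterior <- stage("gibbs_estimate",
                             gibbs_estimate(res$design,
                                            chain_length = mcmc_length,
                                            thin = mcmc_thin,
                                            burn_in = mcmc_burn_in,
                                            seed = seed, vc = res$vc))
      write_tsv_commented(res$posterior$summary,
                          file.path(out_dir, "posterior.tsv"), hdr)
    }
  }

  manifest <- list(package = "qtxmap",
                   version = as.character(utils::packageVersion("qtxmap")),
                   seed = seed, alpha = alpha, n_perm = n_perm,
                   pair_scope = pair_scope,
                   n_records = nrow(pheno), n_markers = ncol(geno$values),
                   stages = stages,
                   n_candidate_loci = nrow(cs$loci),
                   n_candidate_pairs = nrow(cs$pairs))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  res$manifest <- manifest
  invisible(res)
}
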