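#' Reduction in sums of squares for a design block
#'
#' Henderson method III works with reductions `R(model) = y' P y`, the sum
#' of squares captured by the orthogonal projection `P` onto a design's
#' column space. The projector is rank-revealing: singular values below
#' `max(d) * n * eps` count as zero, so the value is invariant to how the
#' block is parameterized.
#'
#' @param y response vector.
#' @param columns design block (matrix, rows aligned with `y`).
#' @param tol optional singular-value tolerance.
#' @return `R(model)`, a scalar in `[0, y'y]`.
#' @export
reduction_ss <- function(y, columns, tol = NULL) {
  columns <- as.matrix(columns)
  if (nrow(columns) != length(y)) stop("dimension mismatch: y vs columns")
  b <- ortho_basis(columns, tol)
  if (b$rank == 0L) return(0)
  sum(crossprod(b$Q, y)^2)
}

#' Henderson method III F-test of nested designs
#'
#' Tests the columns that `full` adds over `reduced` by the difference in
#' reductions:
#' \deqn{F = \frac{[R(full) - R(reduced)] / (r_f - r_r)}
#'                {[y'y - R(full)] / (n - r_f)}}
#' with `r` the column-space ranks. The test depends on the two column
#' spaces only, not on the particular columns spanning them.
#'
#' @param y response vector.
#' @param full design matrix of the full model.
#' @param reduced design matrix of the reduced model (its column space must
#'   be contained in the full model's).
#' @param tol optional singular-value tolerance.
#' @return list with `F`, `df_num`, `df_den`, `p` and `untestable`
#'   (`TRUE` with `F = NA` when nothing is testable: no added rank, or a
#'   saturated full model).
#' @export
henderson_f <- function(y, full, reduced, tol = NULL) {
  n <- length(y)
  bf <- ortho_basis(as.matrix(full), tol)
  br <- ortho_basis(as.matrix(reduced), tol)
  df_num <- bf$rank - br$rank
  df_den <- n - bf$rank
  if (df_num <= 0L || df_den <= 0L)
    return(list(F = NA_real_, df_num = df_num, df_den = df_den,
                p = NA_real_, untestable = TRUE))
  r_full <- sum(crossprod(bf$Q, y)^2)
  r_red <- sum(crossprod(br$Q, y)^2)
  rss <- sum(y^2) - r_full
  F <- ((r_full - r_red) / df_num) / (rss / df_den)
  F <- max(F, 0)  # guard tiny negative rounding
  list(F = F, df_num = df_num, df_den = df_den,
       p = stats::pf(F, df_num, df_den, lower.tail = FALSE),
       untestable = FALSE)
}
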