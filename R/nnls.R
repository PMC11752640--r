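#' Non-negative least squares
#'
#' Solves \eqn{\min_x \|Ax - y\|^2} subject to \eqn{x \ge 0} with the
#' Lawson-Hanson active-set algorithm (compiled). At the solution the KKT
#' conditions hold: the residual gradient is zero (within tolerance) on the
#' positive support and non-negative elsewhere.
#'
#' @param A Numeric matrix (rows = observations).
#' @param y Numeric vector, `length(y) == nrow(A)`.
#' @return Non-negative numeric vector of length `ncol(A)`.
#' @examples
#' nnls_solve(diag(2), c(-1, 3))   # c(0, 3)
#' @export
nnls_solve <- function(A, y) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  y <- as.numeric(y)
  if (nrow(A) != length(y))
    stop("dimension mismatch: nrow(A) = ", nrow(A), ", length(y) = ", length(y))
  if (anyNA(A) || anyNA(y)) stop("nnls_solve: inputs must not contain NA")
  as.numeric(nnls_lh(A, y))
}
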