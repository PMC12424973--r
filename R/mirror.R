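#' Mirror-descent steps for constrained circuit layers
#'
#' Constrained ascent is performed in an unconstrained dual space and mapped
#' back to the primal: `exp` for positive matrices (the sensing matrix W and
#' the glomerular gain) and row-wise `softmax` for simplex-constrained
#' matrices (E and G). The dual update adds `stepSize * gradient` where
#' `gradient` is the ascent direction in the primal space, i.e. classic
#' exponentiated-gradient / entropic mirror ascent.
#'
#' @param dualU Dual matrix (same shape as the primal).
#' @param gradient Ascent direction (primal-space gradient or a
#'   preconditioned version of it).
#' @param stepSize Positive step size.
#' @return A list with the updated `dual` and the re-mapped `primal`.
#' @examples
#' st <- mirrorStepPositive(matrix(0, 2, 2), matrix(1, 2, 2), 0.1)
#' st$primal  # strictly positive
#' @export
mirrorStepPositive <- function(dualU, gradient, stepSize) {
  if (length(dualU) != length(gradient))
    stop("shape mismatch between dual and gradient", call. = FALSE)
  if (any(!is.finite(gradient))) stop("non-finite gradient", call. = FALSE)
  u <- dualU + stepSize * gradient
  u <- pmin(pmax(u, -80), 80)          # keep exp() away from 0/Inf
  list(dual = u, primal = exp(u))
}

#' @rdname mirrorStepPositive
#' @export
mirrorStepSimplex <- function(dualU, gradient, stepSize) {
  if (length(dualU) != length(gradient))
    stop("shape mismatch between dual and gradient", call. = FALSE)
  if (any(!is.finite(gradient))) stop("non-finite gradient", call. = FALSE)
  u <- dualU + stepSize * gradient
  u <- pmin(pmax(u, -80), 80)
  list(dual = u, primal = rowSoftmax(u))
}
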