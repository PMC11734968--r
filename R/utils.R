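`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

# Draw a seed for a sub-stage from a run seed, staying inside 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% 2147483647L
}

upper_pairs <- function(p) {
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}
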