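#' Minimum-cost linear assignment
#'
#' Solves the linear assignment problem exactly (shortest augmenting
#' paths, O(n^3)).  Rectangular matrices are padded with zero-cost dummy
#' rows/columns; `Inf` entries mark forbidden assignments.
#'
#' @param cost numeric cost matrix; `Inf` forbids an assignment.
#' @return An integer vector `a` of length `nrow(cost)`: `a[i]` is the
#'   column assigned to row `i`, or `NA` if row `i` is matched to a dummy
#'   (only possible for rectangular input) or only a forbidden column
#'   remained.
#' @export
solve_lap <- function(cost) {
  if (!is.matrix(cost) || any(is.na(cost))) {
    stop("`cost` must be a numeric matrix without NAs", call. = FALSE)
  }
  nr <- nrow(cost)
  nc <- ncol(cost)
  n <- max(nr, nc)
  finite <- cost[is.finite(cost)]
  big <- if (length(finite)) {
    (max(abs(finite)) + 1) * (n + 1) * 4
  } else {
    1
  }
  sq <- matrix(0, n, n)
  sq[seq_len(nr), seq_len(nc)] <- pmin(cost, big)
  a <- lap_solve_cpp(sq)[seq_len(nr)]
  a[a > nc] <- NA_integer_
  forbidden <- !is.na(a) & !is.finite(cost[cbind(seq_len(nr), a)])
  a[forbidden] <- NA_integer_
  a
}
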