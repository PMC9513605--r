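#' Round half away from zero
#'
#' Base R `round()` rounds half to even, which would map 658.5 to 658.
#' Feature-count arithmetic in this package uses the commercial rule
#' (half away from zero) so that a 75% fraction of an 878-dimensional
#' feature vector keeps 659 features.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @export
#' @examples
#' round_half_up(658.5) # 659
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Derive a child seed from a master seed and a stage offset, staying well
# inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97L + offset * 1009L) %% 2147483647)
}

# Pair indices are row numbers of pair_grid(); kept miRNA-major so that
# index = (mirna_pos - 1) * Nd + disease_pos.
pair_grid <- function(mirna_index, disease_index) {
  tidyr::crossing(mirna = mirna_index, disease = disease_index) |>
    dplyr::arrange(
      match(.data$mirna, mirna_index), match(.data$disease, disease_index)
    )
}

pair_key <- function(mirna, disease) paste(mirna, disease, sep = "\r")

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a single finite number", name))
  }
}

assert_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  stopifnot_scalar_number(x, name)
  lo <- if (open_left) x > 0 else x >= 0
  hi <- if (open_right) x < 1 else x <= 1
  if (!lo || !hi) {
    rlang::abort(sprintf(
      "`%s` must lie in %s0, 1%s", name,
      if (open_left) "(" else "[", if (open_right) ")" else "]"
    ))
  }
}

# Minkowski distance matrix between rows of x (and rows of y if given).
minkowski_dist <- function(x, y = NULL, p = 2) {
  x <- as.matrix(x)
  if (is.null(y)) {
    return(as.matrix(stats::dist(x, method = "minkowski", p = p)))
  }
  y <- as.matrix(y)
  out <- matrix(0, nrow(x), nrow(y))
  for (j in seq_len(nrow(y))) {
    out[, j] <- rowSums(abs(sweep(x, 2, y[j, ], "-"))^p)^(1 / p)
  }
  out
}
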