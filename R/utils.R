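#' @keywords internal
"_PACKAGE"

#' @useDynLib follikel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd
#' @importFrom rlang abort .data
NULL

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Validate a 2-D image carrier: numeric matrix, finite, at least 3x3.
check_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (nrow(img) < 3 || ncol(img) < 3) {
    abort(sprintf("`%s` must be at least 3x3 pixels.", arg))
  }
  if (!all(is.finite(img))) {
    abort(sprintf("`%s` contains non-finite pixel values.", arg))
  }
  invisible(img)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. With seed = NULL the current stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Shift a matrix by (dr, dc) with replicate (nearest-edge) padding.
shift_replicate <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) + dr, 1L), H)
  ci <- pmin(pmax(seq_len(W) + dc, 1L), W)
  m[ri, ci, drop = FALSE]
}

# 4-neighbour Laplacian with replicate boundary handling.
laplacian4 <- function(m) {
  shift_replicate(m, -1L, 0L) + shift_replicate(m, 1L, 0L) +
    shift_replicate(m, 0L, -1L) + shift_replicate(m, 0L, 1L) - 4 * m
}

# Validate a point-set tibble/data.frame with 1-based `row`, `col` columns.
check_points <- function(pts, arg = "points") {
  if (!is.data.frame(pts) || !all(c("row", "col") %in% names(pts))) {
    abort(sprintf("`%s` must be a data frame with `row` and `col` columns.", arg))
  }
  if (nrow(pts) == 0) {
    abort(sprintf("`%s` must contain at least one point.", arg))
  }
  invisible(pts)
}
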