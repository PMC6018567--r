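#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm anova vcov coef pt qt qnorm rnorm rlnorm plogis
#'   chisq.test p.adjust sd quantile setNames
#' @importFrom utils head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_iterlesion <- function(msg, class) {
  stop(structure(class = c(class, "iterlesion_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# linear voxel index (column-major, 1-based) from an m x 3 coordinate matrix
coords_to_linear <- function(coords, dim3) {
  coords[, 1L] + dim3[1L] * (coords[, 2L] - 1L) +
    dim3[1L] * dim3[2L] * (coords[, 3L] - 1L)
}

# voxel (1-based) indices -> world mm via the affine (0-based voxel convention)
voxel_to_world <- function(coords, affine) {
  v0 <- cbind(coords - 1L, 1)
  w <- v0 %*% t(affine)
  w[, 1:3, drop = FALSE]
}

# all n! permutations of 1:n as an n! x n matrix (small n only)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    blk <- nrow(sub)
    out[row + seq_len(blk), 1L] <- i
    out[row + seq_len(blk), -1L] <- matrix(rest[sub], blk, n - 1L)
    row <- row + blk
  }
  out
}

# count, for each x, how many elements of null are >= x; ties count as
# exceedances, compared at a small numerical tolerance so that structurally
# tied statistics computed along different floating-point paths agree
count_ge <- function(x, null, tol = 1e-8) {
  s <- sort(null)
  length(null) - findInterval(x - tol * pmax(1, abs(x)), s, left.open = TRUE)
}

# independent child seeds derived from a master seed
child_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
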