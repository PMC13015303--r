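#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup left_join bind_rows
#' @importFrom purrr map map_dbl map_int map2 imap
#' @importFrom stats rnorm runif sd cor quantile lm coef pt p.adjust dnorm var
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.", class = "netdax_error_seed")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stream of child seeds from a master seed (keeps every sub-stage
# independently reproducible). Values stay below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_positive_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 || x != floor(x)) {
    abort(sprintf("`%s` must be a positive integer.", name),
          class = "netdax_error_argument")
  }
  as.integer(x)
}

# Add-one permutation p-value: p = (1 + #{null >= obs}) / (1 + n_perm).
perm_pvalue <- function(observed, null) {
  (1 + sum(null >= observed)) / (1 + length(null))
}

# Pairwise Euclidean distances between rows of a and rows of b.
cross_dist <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Uniform random 3D rotation matrix (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
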