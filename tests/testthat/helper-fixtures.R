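# Shared fixtures, built once per test run.

toy_geom <- function(n_vertices = 400, n_parcels = 20, seed = 1) {
  key <- sprintf("geom_%d_%d_%d", n_vertices, n_parcels, seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make_geometry(n_vertices, n_parcels, seed)
  }
  .fixture_cache[[key]]
}

.fixture_cache <- new.env()

# Brute-force Dice between two index-set masks (the oracle used against the
# matrix implementation).
dice_oracle <- function(a, b) {
  ia <- which(a)
  ib <- which(b)
  if (length(ia) + length(ib) == 0) return(0)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

# Brute-force correspondence metrics from a Dice matrix via explicit loops.
profile_oracle <- function(D) {
  K <- nrow(D)
  M <- ncol(D)
  cnr <- numeric(M)
  for (m in seq_len(M)) {
    best <- -Inf
    for (k in seq_len(K)) if (D[k, m] > best) best <- D[k, m]
    cnr[m] <- best
  }
  nn <- 0
  for (k in seq_len(K)) {
    best <- -Inf
    for (m in seq_len(M)) if (D[k, m] > best) best <- D[k, m]
    nn <- nn + (1 - best)
  }
  list(cnr = cnr, normativity = sum(cnr) / M, non_normativity = nn / K)
}

random_support_matrix <- function(k, v, p = 0.3) {
  matrix(runif(k * v) < p, k, v)
}
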