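# Internal numerical helpers shared across modules.

# Matrix exponential of a rate matrix via eigendecomposition, with a dense
# Pade fallback when the eigenbasis is ill-conditioned. DEC state spaces are
# small (<= a few hundred states) so dense methods are fine; the eigen route
# lets us reuse one decomposition for many branch lengths.
.eigen_decompose <- function(Q) {
  eg <- eigen(Q)
  V <- eg$vectors
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi)) return(NULL)
  # reciprocal condition check: a near-defective Q makes eigen-expm unstable
  if (!all(is.finite(Mod(eg$values))) ||
      max(Mod(V)) * max(Mod(Vi)) > 1e12) return(NULL)
  list(values = eg$values, V = V, Vi = Vi, Q = Q)
}

.expm_from_eigen <- function(dec, t) {
  P <- Re(dec$V %*% (exp(dec$values * t) * dec$Vi))
  # clamp tiny negative entries from roundoff
  P[P < 0] <- 0
  P
}

.expm_safe <- function(Q, t, dec = NULL) {
  if (t == 0) return(diag(nrow(Q)))
  if (!is.null(dec)) {
    P <- .expm_from_eigen(dec, t)
    rs <- rowSums(P)
    if (all(is.finite(rs)) && max(abs(rs - 1)) < 1e-7) return(P)
  }
  P <- as.matrix(Matrix::expm(Q * t))
  P[P < 0] <- 0
  P
}

# Deterministic child stream seeds derived from a master seed; keeps every
# derived seed a valid 32-bit integer.
.child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 2147483647 / 127773) %% 2147483629) + 1L
}

# Evaluate a function under a temporary RNG state, restoring the caller's.
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
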