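## Internal numerical helpers shared across modules.

#' Legendre polynomials and derivatives by recurrence
#'
#' Computes P_n(x) and P_n'(x) for n = 1..nmax at the points `x` using
#' the Bonnet recurrence for P_n and the stable derivative recurrence
#' P'_{n+1} = P'_{n-1} + (2n+1) P_n, which remains exact at |x| = 1.
#'
#' @param x numeric vector in [-1, 1]
#' @param nmax highest order
#' @return list with matrices `p` and `dp`, each length(x) x nmax
#' @keywords internal
#' @noRd
legendre_table <- function(x, nmax) {
  m <- length(x)
  p <- matrix(0, m, nmax)
  dp <- matrix(0, m, nmax)
  pm1 <- rep(1, m)        # P_0
  p[, 1] <- x             # P_1
  dpm1 <- rep(0, m)       # P'_0
  dp[, 1] <- 1            # P'_1
  if (nmax >= 2) {
    for (n in 1:(nmax - 1)) {
      p[, n + 1] <- ((2 * n + 1) * x * p[, n] - n * pm1) / (n + 1)
      dp[, n + 1] <- dpm1 + (2 * n + 1) * p[, n]
      pm1 <- p[, n]
      dpm1 <- dp[, n]
    }
  }
  list(p = p, dp = dp)
}

#' Near-uniform directions on the unit sphere (Fibonacci lattice)
#' @param n number of directions
#' @param hemisphere if TRUE restrict to z >= 0 (upper hemisphere)
#' @return n x 3 matrix of unit vectors
#' @keywords internal
#' @noRd
fibonacci_sphere <- function(n, hemisphere = FALSE) {
  i <- seq_len(n) - 0.5
  z <- if (hemisphere) 1 - i / n else 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Amari index between an unmixing and a mixing matrix
#'
#' Permutation- and scale-invariant separation error of `W %*% A`,
#' normalized to [0, 1]; 0 means perfect recovery up to permutation and
#' scaling.
#'
#' @param W estimated unmixing matrix (k x k)
#' @param A true mixing matrix (k x k)
#' @return scalar in [0, 1]
#' @export
amari_index <- function(W, A) {
  P <- abs(W %*% A)
  k <- nrow(P)
  stopifnot(k == ncol(P), k >= 2)
  rterm <- sum(rowSums(P) / apply(P, 1, max) - 1)
  cterm <- sum(colSums(P) / apply(P, 2, max) - 1)
  (rterm + cterm) / (2 * k * (k - 1))
}

#' Moore-Penrose pseudo-inverse via SVD
#' @keywords internal
#' @noRd
pinv <- function(x, tol = NULL) {
  s <- svd(x)
  if (is.null(tol)) tol <- max(dim(x)) * max(s$d) * .Machine$double.eps
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(x), nrow(x)))
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

#' Excess-free kurtosis (fourth standardized moment)
#' @keywords internal
#' @noRd
kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(0)
  mean(x^4) / m2^2
}

#' z-score a vector; zero-variance input maps to all zeros
#' @keywords internal
#' @noRd
zscore0 <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Stable per-call RNG seeding without touching the caller's stream
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a stream of child seeds from a master seed
#' @keywords internal
#' @noRd
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## package-local cache (montage grid gains, shell transfer coefficients)
.p3cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  if (!is.null(.p3cache[[key]])) return(.p3cache[[key]])
  val <- compute()
  assign(key, val, envir = .p3cache)
  val
}
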