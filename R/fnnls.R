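#' Fast non-negative least squares (FNNLS)
#'
#' Solves \eqn{\min_x \|Ax - b\|^2} subject to \eqn{x \ge 0} from the
#' normal-equation inputs \eqn{A^\top A} and \eqn{A^\top b}, using the
#' Bro & De Jong active-set scheme (the fast variant of Lawson-Hanson
#' NNLS used inside the ALS optimization). The returned solution satisfies
#' the KKT conditions to within `tol`.
#'
#' @param AtA symmetric positive semidefinite matrix (`p x p`).
#' @param Atb numeric vector of length `p`.
#' @param tol dual-feasibility tolerance; defaults to
#'   `10 * p * eps * max(diag(AtA))`.
#' @param max_iter active-set iteration cap.
#' @return Non-negative numeric vector of length `p`.
#' @examples
#' fnnls(diag(2), c(1, -1))  # c(1, 0)
#' @export
fnnls <- function(AtA, Atb, tol = NULL, max_iter = NULL) {
  AtA <- as.matrix(AtA)
  Atb <- as.numeric(Atb)
  p <- length(Atb)
  if (nrow(AtA) != p || ncol(AtA) != p)
    stop("AtA must be ", p, " x ", p, " to match Atb")
  tol <- tol %||% (10 * p * .Machine$double.eps * max(diag(AtA), 1e-300))
  max_iter <- max_iter %||% (30L * p)
  x <- numeric(p)
  P <- logical(p)
  w <- Atb
  it <- 0L
  while (any(!P) && any(w[!P] > tol) && it < max_iter) {
    it <- it + 1L
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      s <- numeric(p)
      s[P] <- solve(AtA[P, P, drop = FALSE], Atb[P])
      if (all(s[P] > 0)) {
        x <- s
        break
      }
      neg <- P & (s <= 0)
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      P[P & (x <= .Machine$double.eps * max(abs(x)))] <- FALSE
      x[!P] <- 0
    }
    w <- Atb - as.numeric(AtA %*% x)
  }
  x
}

# Column-wise non-negative least squares with a shared Gram matrix:
# solves min ||A X - B||^2, X >= 0, given AtA (p x p) and AtB (p x ncol).
# Exact vectorized enumeration for p <= 2 (the two-component MCR case);
# per-column fnnls otherwise.
nnls_cols <- function(AtA, AtB) {
  p <- nrow(AtB)
  if (p == 1L) {
    a <- AtA[1L, 1L]
    return(matrix(pmax(0, AtB[1L, ] / a), 1L, ncol(AtB)))
  }
  if (p == 2L) {
    a11 <- AtA[1L, 1L]; a22 <- AtA[2L, 2L]; a12 <- AtA[1L, 2L]
    det <- a11 * a22 - a12^2
    b1 <- AtB[1L, ]; b2 <- AtB[2L, ]
    if (det > 1e-14 * max(a11 * a22, 1e-300)) {
      x1 <- (a22 * b1 - a12 * b2) / det
      x2 <- (a11 * b2 - a12 * b1) / det
      interior <- x1 >= 0 & x2 >= 0
    } else {
      x1 <- x2 <- numeric(length(b1))
      interior <- rep(FALSE, length(b1))
    }
    # boundary minima on each axis (1D clipped least squares); exact:
    # the feasible boundary consists of the two coordinate rays
    e1 <- if (a11 > 0) pmax(0, b1 / a11) else numeric(length(b1))
    e2 <- if (a22 > 0) pmax(0, b2 / a22) else numeric(length(b1))
    q1 <- 0.5 * a11 * e1^2 - b1 * e1
    q2 <- 0.5 * a22 * e2^2 - b2 * e2
    use1 <- q1 <= q2
    X <- rbind(ifelse(interior, x1, ifelse(use1, e1, 0)),
               ifelse(interior, x2, ifelse(use1, 0, e2)))
    return(X)
  }
  apply(AtB, 2L, function(b) fnnls(AtA, b))
}
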