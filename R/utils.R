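# small internal geometry/RNG helpers shared across modules

.rand_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n2 <- sum(v^2)
    if (n2 > 1e-12) return(v / sqrt(n2))
  }
}

# Rodrigues rotation matrix about `axis` by `theta`
.rot_matrix <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  ct <- cos(theta)
  st <- sin(theta)
  K <- matrix(c(0, -a[3], a[2],
                a[3], 0, -a[1],
                -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * tcrossprod(a)
}

.rand_rotation <- function() .rot_matrix(.rand_unit(), stats::runif(1, 0, 2 * pi))

# center-of-geometry Rg of a point set (rows = points)
.rg_points <- function(X) {
  cm <- colMeans(X)
  sqrt(mean(rowSums(sweep(X, 2, cm)^2)))
}

# minimum distance between two point sets (rows = points)
.min_cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(max(0, min(d2)))
}

# all pairwise distances between two point sets under cubic minimum image
# (L = NULL means open boundary); returns |A| x |B| matrix
.cross_dist_pbc <- function(A, B, L = NULL) {
  if (is.null(L)) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    return(sqrt(pmax(d2, 0)))
  }
  n <- nrow(A)
  m <- nrow(B)
  d2 <- matrix(0, n, m)
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    dk <- dk - L * round(dk / L)
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

.stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop("`", name, "` must be a single positive finite number")
  invisible(x)
}
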