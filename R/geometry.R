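# Small rigid-body geometry helpers shared across modules.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize zero vector")
  v / n
}

#' Rigid transform
#'
#' A rotation plus translation, applied to row-wise coordinate matrices as
#' `x %*% t(R) + t`.
#'
#' @param R 3x3 proper rotation matrix.
#' @param t length-3 translation vector.
#' @return Object of class `kgs_transform`.
#' @export
kgs_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  stopifnot(all(dim(R) == c(3L, 3L)), length(t) == 3L)
  structure(list(R = R, t = as.numeric(t)), class = "kgs_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 matrix (or length-3 vector) of coordinates.
#' @param transform a [kgs_transform()].
#' @return Transformed coordinates, same shape as input.
#' @export
apply_transform <- function(xyz, transform) {
  vec <- is.null(dim(xyz))
  if (vec) xyz <- matrix(xyz, nrow = 1L)
  out <- xyz %*% t(transform$R) + matrix(transform$t, nrow(xyz), 3L, byrow = TRUE)
  if (vec) drop(out) else out
}

#' Invert a rigid transform
#' @param transform a [kgs_transform()].
#' @return The inverse `kgs_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$R)
  kgs_transform(Rt, -drop(Rt %*% transform$t))
}

#' Draw a uniformly random rigid transform
#'
#' Rotation sampled uniformly from SO(3) (via QR of a Gaussian matrix with
#' sign fix), translation uniform in a cube. Uses the current RNG stream.
#'
#' @param max_translation half-width of the translation cube (A).
#' @return A [kgs_transform()].
#' @export
random_transform <- function(max_translation = 20) {
  M <- matrix(rnorm(9L), 3L, 3L)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  d[d == 0] <- 1
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  kgs_transform(Q, runif(3L, -max_translation, max_translation))
}

# Kabsch least-squares superposition: returns the proper-rotation rigid
# transform mapping q onto p (both m x 3). With fewer than 3 points (or on
# request) falls back to translation-only alignment of centroids.
kabsch <- function(p, q, allow_translation_only = TRUE) {
  p <- as.matrix(p); q <- as.matrix(q)
  stopifnot(nrow(p) == nrow(q), ncol(p) == 3L, ncol(q) == 3L)
  m <- nrow(p)
  pc <- colMeans(p); qc <- colMeans(q)
  if (m < 3L) {
    if (!allow_translation_only) stop("need >= 3 point pairs for a rotation")
    return(kgs_transform(diag(3), pc - qc))
  }
  P0 <- sweep(p, 2L, pc)
  Q0 <- sweep(q, 2L, qc)
  H <- t(Q0) %*% P0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  kgs_transform(R, pc - drop(R %*% qc))
}
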