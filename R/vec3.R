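# Small 3-vector helpers. Scene coordinates are millimetres, right-handed,
# y up, ground plane y = 0.

v3 <- function(x, y, z) {
  p <- c(as.numeric(x), as.numeric(y), as.numeric(z))
  if (any(!is.finite(p))) stop("vec3 components must be finite")
  p
}

vdot <- function(a, b) sum(a * b)

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  a / n
}

#' @noRd
is_unit <- function(a, tol = 1e-6) abs(vnorm(a) - 1) < tol

# Deterministic orthonormal in-plane basis (u, v) for a unit normal n:
# reference axis is whichever world axis is least aligned with n.
plane_basis <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- vunit(vcross(ref, n))
  v <- vcross(n, u)
  list(u = u, v = v)
}

# Rodrigues rotation of vector p about unit axis by angle (radians).
rotate_about <- function(p, axis, angle) {
  axis <- vunit(axis)
  ca <- cos(angle); sa <- sin(angle)
  p * ca + vcross(axis, p) * sa + axis * vdot(axis, p) * (1 - ca)
}
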