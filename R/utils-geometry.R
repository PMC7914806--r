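# Small vector / quaternion helpers shared across modules. All direction
# vectors are rows of an n x 3 matrix; quaternions are rows of an n x 4
# matrix in (w, x, y, z) order.

#' @keywords internal
#' @noRd
as_mat3 <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3L, byrow = TRUE)
  storage.mode(v) <- "double"
  v
}

#' Row-wise Euclidean norm
#' @noRd
row_norm <- function(m) {
  m <- as_mat3(m)
  sqrt(rowSums(m * m))
}

#' Row-wise renormalisation to unit length; zero rows stay zero
#' @noRd
unit_rows <- function(m) {
  m <- as_mat3(m)
  n <- row_norm(m)
  ok <- n > 0
  m[ok, ] <- m[ok, , drop = FALSE] / n[ok]
  m
}

#' Row-wise cross product
#' @noRd
cross_rows <- function(a, b) {
  a <- as_mat3(a); b <- as_mat3(b)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Row-wise dot product
#' @noRd
dot_rows <- function(a, b) {
  a <- as_mat3(a); b <- as_mat3(b)
  rowSums(a * b)
}

#' Rotate rows of `v` about unit axis `axis` by `angle_rad` (Rodrigues)
#' @noRd
rotate_rows <- function(v, axis, angle_rad) {
  v <- as_mat3(v)
  n <- nrow(v)
  axis <- as_mat3(axis)
  if (nrow(axis) == 1L && n > 1L) axis <- axis[rep(1L, n), , drop = FALSE]
  if (length(angle_rad) == 1L) angle_rad <- rep(angle_rad, n)
  ca <- cos(angle_rad); sa <- sin(angle_rad)
  k_cross_v <- cross_rows(axis, v)
  k_dot_v <- dot_rows(axis, v)
  v * ca + k_cross_v * sa + axis * (k_dot_v * (1 - ca))
}

#' Orthonormal tangent basis (e1, e2) for each unit direction row
#'
#' e1 is chosen in the plane spanned by the direction and the global +y axis
#' (so it points "screen-horizontal" for forward gaze); e2 completes the
#' right-handed triad. Directions parallel to +y fall back to the +x helper.
#' @noRd
tangent_basis <- function(dir) {
  dir <- unit_rows(dir)
  n <- nrow(dir)
  up <- matrix(rep(c(0, 1, 0), each = n), ncol = 3L)
  # replace helper where dir is (anti)parallel to up
  deg <- abs(dot_rows(dir, up)) > 1 - 1e-9
  up[deg, ] <- matrix(rep(c(1, 0, 0), sum(deg)), ncol = 3L, byrow = TRUE)
  e1 <- unit_rows(cross_rows(up, dir))
  e2 <- cross_rows(dir, e1)
  list(e1 = e1, e2 = e2)
}

# ---- quaternions (w, x, y, z), unit norm ------------------------------------

#' @noRd
quat_from_axis_angle <- function(axis, angle_rad) {
  axis <- unit_rows(axis)
  n <- max(nrow(axis), length(angle_rad))
  if (nrow(axis) == 1L) axis <- axis[rep(1L, n), , drop = FALSE]
  if (length(angle_rad) == 1L) angle_rad <- rep(angle_rad, n)
  half <- angle_rad / 2
  cbind(cos(half), axis * sin(half))
}

#' @noRd
quat_conj <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 4L, byrow = TRUE)
  cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4])
}

#' Hamilton product, row-wise
#' @noRd
quat_mult <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 4L, byrow = TRUE)
  if (is.null(dim(b))) b <- matrix(b, ncol = 4L, byrow = TRUE)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  cbind(w, x, y, z, deparse.level = 0)
}

#' Rotate vector rows by quaternion rows: v' = q v q*
#' @noRd
quat_rotate <- function(q, v) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 4L, byrow = TRUE)
  v <- as_mat3(v)
  if (nrow(q) == 1L && nrow(v) > 1L) q <- q[rep(1L, nrow(v)), , drop = FALSE]
  u <- q[, 2:4, drop = FALSE]
  w <- q[, 1]
  t2 <- 2 * cross_rows(u, v)
  v + w * t2 + cross_rows(u, t2)
}

#' Run `expr` under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Format numeric columns for text output at full round-trip precision
#' @noRd
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.12g", v)
  }, character(1))
  out
}
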