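# Independent brute-force oracles and fixture builders.
#
# The oracles deliberately avoid the package's computation path: distances
# are expanded coordinate by coordinate, angles use atan2 of the cross and
# dot products (the package uses clamped acos of the normalized dot), and
# aggregation is re-done from raw vectors.

oracle_dist <- function(p, q) {
  unname(sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2 + (p[3] - q[3])^2))
}

oracle_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# angle at `v` between rays to `a` and `b`, via atan2(|u x w|, u.w)
oracle_angle <- function(a, v, b) {
  u <- a - v
  w <- b - v
  atan2(sqrt(sum(oracle_cross(u, w)^2)), sum(u * w)) * 180 / pi
}

# the semiangle statistic recomputed directly from raw coordinates
oracle_semiangles <- function(cdr, me, cdl) {
  cdm <- (cdr + cdl) / 2
  list(full = oracle_angle(cdr, me, cdl),
       semi_r = oracle_angle(cdr, me, cdm),
       semi_l = oracle_angle(cdl, me, cdm))
}

# uniform random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_out <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_out)
  Q <- Q %*% diag(sign(diag(qr.R(qr_out))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# apply a rigid motion (rotation R then translation tr) to a landmark_set
transform_set <- function(s, R, tr) {
  pts <- t(R %*% t(s$points)) + matrix(tr, nrow(s$points), 3, byrow = TRUE)
  rownames(pts) <- rownames(s$points)
  landmark_set(s$subject_id, pts)
}

# reflect every point across the plane through `origin` with unit normal
# `normal`, and swap R/L landmark codes
mirror_set <- function(s, normal = c(1, 0, 0), origin = c(0, 0, 0)) {
  n <- normal / sqrt(sum(normal^2))
  pts <- t(apply(s$points, 1, function(p) p - 2 * sum((p - origin) * n) * n))
  rownames(pts) <- mirror_partner(rownames(s$points))
  landmark_set(s$subject_id, pts)
}

# a random non-degenerate complete landmark set: the template jittered by
# a few mm so every configuration stays anatomically shaped
random_landmark_set <- function(jitter_sd = 3, subject_id = "rnd") {
  t <- symmetric_template(subject_id)
  pts <- t$points + matrix(rnorm(length(t$points), sd = jitter_sd),
                           nrow = nrow(t$points))
  rownames(pts) <- rownames(t$points)
  landmark_set(subject_id, pts)
}
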