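# Geometry and RNG helpers shared across the grid, search and fixture code.

# Rotation matrix from a unit quaternion (w, x, y, z).
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < 1e-12) c(1, 0, 0, 0) else q / n
}

# Hamilton product p * q.
quat_multiply <- function(p, q) {
  c(
    p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1]
  )
}

# Uniform random unit quaternion (Shoemake's subgroup algorithm).
random_quaternion <- function() {
  u <- runif(3)
  c(
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3])
  )
}

# Quaternion for rotation by `angle` about unit `axis`.
axis_angle_quat <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# Rotate rows of an n x 3 matrix about the axis p1 -> p2 by `angle` (radians).
rotate_about_axis <- function(coords, p1, p2, angle) {
  axis <- p2 - p1
  R <- quat_to_matrix(axis_angle_quat(axis, angle))
  sweep(sweep(coords, 2, p1) %*% t(R), 2, p1, `+`)
}

wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  # map the -pi endpoint to +pi so angles live in (-pi, pi]
  w[w <= -pi] <- pi
  w
}

# Counter-based child seed derivation: independent streams from one master
# seed, always a positive 32-bit integer.
derive_seed <- function(master, index) {
  m <- 2147483629
  s <- (as.double(master) %% m) * 48271 + as.double(index) * 10007 + 1
  as.integer(s %% m) + 1L
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}
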