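# small in-code fixtures shared across test files

# a single-frame trajectory from a beads x 3 coordinate matrix
traj_from_frame <- function(m, ...) {
  calpha_trajectory(array(m, dim = c(1, nrow(m), 3)), ...)
}

# straight chain of n beads spaced `step` apart on the x axis
straight_chain <- function(n, step = 3.8) {
  cbind((seq_len(n) - 1) * step, 0, 0)
}

# random rigid-body transform applied to every frame of a trajectory
apply_rigid <- function(traj, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3)
  qr_r <- qr(m)
  rot <- qr.Q(qr_r)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  shift <- rnorm(3) * 10
  co <- traj$coords
  for (f in seq_len(dim(co)[1]))
    co[f, , ] <- co[f, , ] %*% rot + matrix(shift, dim(co)[2], 3, byrow = TRUE)
  calpha_trajectory(co, temperature = traj$temperature,
                    replica = traj$replica, frame_dt = traj$frame_dt,
                    bond_length = traj$bond_length)
}

# brute-force signed dihedral via explicit normal-vector construction,
# independent of the package's row-vectorised implementation
oracle_dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  ang <- acos(max(-1, min(1, sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2)))))
  if (sum(cross(n1, n2) * b2) < 0) ang <- -ang
  ang
}
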