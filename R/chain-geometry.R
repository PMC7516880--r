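#' Construct a C-alpha trajectory
#'
#' The basic container of the package: an ordered set of frames of
#' 3-D C-alpha (bead) coordinates for one replica, with its temperature
#' label, replica id and frame time step.
#'
#' @param coords numeric array, frames x beads x 3, in Angstrom. A single
#'   beads x 3 matrix is promoted to one frame.
#' @param temperature temperature label (opaque string, e.g. "300K").
#' @param replica replica identifier.
#' @param frame_dt time between frames in ns.
#' @param bond_length nominal consecutive-bead distance in Angstrom, if
#'   known (recorded, not enforced).
#' @param window optional time-interval label.
#' @return an object of class `calpha_trajectory`.
#' @export
calpha_trajectory <- function(coords, temperature = NA_character_,
                              replica = NA_integer_, frame_dt = 1,
                              bond_length = NA_real_, window = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1, dim(coords)))
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop("coords must be a frames x beads x 3 array", call. = FALSE)
  if (dim(coords)[1] < 1 || dim(coords)[2] < 4)
    stop("need at least 1 frame and 4 beads", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("all coordinates must be finite", call. = FALSE)
  structure(list(coords = coords, temperature = temperature,
                 replica = replica, frame_dt = frame_dt,
                 bond_length = bond_length, window = window),
            class = "calpha_trajectory")
}

#' @export
print.calpha_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("C-alpha trajectory: %d frames x %d beads (%s, replica %s, dt %g ns)\n",
              d[1], d[2], x$temperature, x$replica, x$frame_dt))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]
n_beads <- function(traj) dim(traj$coords)[2]

#' Per-frame end-to-end vectors of a chain
#'
#' The end-to-end vector of a chain of beads r_0 .. r_N is
#' \eqn{\vec R = \vec r_N - \vec r_0}, equal to the sum of the bond
#' vectors. Returned per frame with its Euclidean norm.
#'
#' @param traj a [calpha_trajectory()].
#' @return an object of class `end_to_end_series` with fields `vectors`
#'   (frames x 3) and `norms` (length frames), both in Angstrom.
#' @export
end_to_end_series <- function(traj) {
  stopifnot(inherits(traj, "calpha_trajectory"))
  nb <- n_beads(traj)
  if (nb < 2) stop("need at least 2 beads", call. = FALSE)
  v <- traj$coords[, nb, , drop = FALSE] - traj$coords[, 1, , drop = FALSE]
  v <- matrix(v, ncol = 3)
  structure(list(vectors = v, norms = sqrt(rowSums(v^2))),
            class = "end_to_end_series")
}

#' Root mean square end-to-end distance
#'
#' \eqn{\sqrt{\langle R^2\rangle}} over a frame window. For an ideal
#' (freely jointed) chain of N bonds of length tau the expectation of
#' \eqn{\langle R^2 \rangle} is \eqn{N\tau^2}.
#'
#' @param series an [end_to_end_series()].
#' @param window integer frame indices; default all frames.
#' @return RMS end-to-end distance in Angstrom.
#' @export
rms_end_to_end <- function(series, window = NULL) {
  stopifnot(inherits(series, "end_to_end_series"))
  r <- series$norms
  if (!is.null(window)) r <- r[window]
  if (length(r) == 0) stop("empty frame window", call. = FALSE)
  sqrt(mean(r^2))
}

#' Flory-De Gennes size exponent
#'
#' From the scaling law \eqn{R \sim \tau N^{\mu}}, the size exponent is
#' estimated as \eqn{\mu = \ln(R/\tau) / \ln(N)} with R the RMS
#' end-to-end distance, tau the bond length and N the chain-size
#' parameter. The ratio of logarithms is base-independent; natural logs
#' are used. mu = 1/2 for an ideal chain; collapsed or confined chains
#' fall below 1/2. N is a required explicit argument: printed summary
#' tables for albumin are reproduced with N = 576 even though the chain
#' has 578 bonds, so no default is assumed.
#'
#' @param r_rms RMS end-to-end distance in Angstrom (> 0).
#' @param tau bond length in Angstrom (> 0).
#' @param n_bonds chain-size parameter N (>= 2).
#' @return an object of class `flory_estimate` with fields `mu`, `r_rms`,
#'   `tau`, `n_bonds`.
#' @export
flory_exponent <- function(r_rms, tau, n_bonds) {
  if (any(r_rms <= 0) || tau <= 0)
    stop("r_rms and tau must be positive", call. = FALSE)
  if (n_bonds < 2) stop("n_bonds must be >= 2", call. = FALSE)
  structure(list(mu = log(r_rms / tau) / log(n_bonds),
                 r_rms = r_rms, tau = tau, n_bonds = n_bonds,
                 log_base_note = "natural log (ratio is base-independent)"),
            class = "flory_estimate")
}

#' @export
print.flory_estimate <- function(x, ...) {
  cat(sprintf("Flory-De Gennes size exponent: mu = %.4f  (R = %g A, tau = %g A, N = %d)\n",
              x$mu, x$r_rms, x$tau, as.integer(x$n_bonds)))
  invisible(x)
}

# Optimal rotation (Kabsch, via SVD) aligning moving onto target, both
# already centred; applied to row-vector coordinates as x %*% R.
kabsch_rotation <- function(moving, target) {
  h <- crossprod(moving, target)
  s <- svd(h)
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Root mean squared displacement series
#'
#' Per frame, \eqn{RMSD = \sqrt{\sum_i R_i \cdot R_i / n}} where
#' \eqn{R_i} is bead i's displacement from the reference after the chosen
#' alignment. The alignment conventions are: `"none"` (raw displacement
#' from the reference coordinates), `"centroid"` (default; both structures
#' translated to a common centroid before differencing) and
#' `"centroid+rotation"` (full Kabsch superposition).
#'
#' @param traj a [calpha_trajectory()].
#' @param reference beads x 3 matrix, or a frame index into `traj`
#'   (default 1).
#' @param alignment one of `"centroid"`, `"none"`, `"centroid+rotation"`.
#' @return numeric vector, one RMSD in Angstrom per frame.
#' @export
rmsd_series <- function(traj, reference = 1,
                        alignment = c("centroid", "none", "centroid+rotation")) {
  stopifnot(inherits(traj, "calpha_trajectory"))
  alignment <- match.arg(alignment)
  nb <- n_beads(traj)
  ref <- if (is.matrix(reference)) reference else traj$coords[reference, , ]
  if (nrow(ref) != nb)
    stop("reference bead count does not match trajectory", call. = FALSE)
  ref_c <- sweep(ref, 2, colMeans(ref))
  vapply(seq_len(n_frames(traj)), function(f) {
    x <- traj$coords[f, , ]
    disp <- switch(alignment,
      none = x - ref,
      centroid = sweep(x, 2, colMeans(x)) - ref_c,
      `centroid+rotation` = {
        xc <- sweep(x, 2, colMeans(x))
        xc %*% kabsch_rotation(xc, ref_c) - ref_c
      })
    sqrt(sum(disp^2) / nb)
  }, numeric(1))
}

# angle at b from a-b-c, in [0, pi]; NA for degenerate (zero-length) arms.
planar_angle_rows <- function(a, b, c) {
  u <- a - b; v <- c - b
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  cosang <- rowSums(u * v) / (nu * nv)
  out <- acos(pmin(1, pmax(-1, cosang)))
  out[nu < 1e-12 | nv < 1e-12] <- NA_real_
  out
}

# signed dihedral for rows of a-b-c-d, IUPAC convention (cis = 0), (-pi, pi]
dihedral_rows <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
              b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
              b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
  n2 <- cbind(b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
              b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
              b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
  nb2 <- sqrt(rowSums(b2^2))
  y <- nb2 * rowSums(b1 * n2)
  x <- rowSums(n1 * n2)
  out <- atan2(y, x)
  bad <- nb2 < 1e-12 | sqrt(rowSums(n1^2)) < 1e-12 | sqrt(rowSums(n2^2)) < 1e-12
  out[bad] <- NA_real_
  out[out <= -pi + 1e-15] <- pi       # domain (-pi, pi]
  out
}

#' Backbone angles along the C-alpha trace
#'
#' For each frame, the planar backbone angle phi_i at each interior bead i
#' (the angle subtended at bead i by beads i-1 and i+1, in `[0, pi]`) and
#' the signed dihedral psi_i over beads (i-1, i, i+1, i+2) in `(-pi, pi]`
#' with the IUPAC sign convention (cis = 0). Degenerate geometry
#' (coincident consecutive beads) yields NA for the affected angle rather
#' than an error.
#'
#' @param traj a [calpha_trajectory()].
#' @return an object of class `angle_series` with matrices `phi`
#'   (frames x (beads-2)) and `psi` (frames x (beads-3)), in radians.
#' @export
backbone_angles <- function(traj) {
  stopifnot(inherits(traj, "calpha_trajectory"))
  nb <- n_beads(traj); nf <- n_frames(traj)
  if (nb < 4) stop("need at least 4 beads", call. = FALSE)
  co <- traj$coords
  flat <- function(i) matrix(co[, i, ], ncol = 3)  # frames*|i| rows
  idx <- 2:(nb - 1)
  phi <- planar_angle_rows(flat(idx - 1), flat(idx), flat(idx + 1))
  idx2 <- 2:(nb - 2)
  psi <- dihedral_rows(flat(idx2 - 1), flat(idx2), flat(idx2 + 1), flat(idx2 + 2))
  structure(list(phi = matrix(phi, nrow = nf),
                 psi = matrix(psi, nrow = nf),
                 index_convention = "phi at interior beads 2..n-1; psi over beads (i-1,i,i+1,i+2) for i = 2..n-2"),
            class = "angle_series")
}

#' Bonded-term force-field parameters
#'
#' Parameter set for the bonded part of an AMBER-style potential: harmonic
#' bonds \eqn{k_b (r - r_{eq})^2}, harmonic angles
#' \eqn{k_\phi(\phi - \phi_{eq})^2} and cosine dihedrals
#' \eqn{(V_n/2)(1 + \cos(n\psi - \gamma))}. Term indices refer to the
#' geometric elements of a frame: bond t spans beads (t, t+1), angle t is
#' the planar angle at bead t+1, dihedral t spans beads (t .. t+3).
#' Non-bonded terms (van der Waals, Coulomb) are out of scope.
#'
#' @param bonds data.frame with columns `index`, `kb`, `req`.
#' @param angles data.frame with columns `index`, `kphi`, `phieq`.
#' @param dihedrals data.frame with columns `index`, `vn`, `n`, `gamma`
#'   (gamma either 0 or pi).
#' @return an object of class `bonded_energy_params`.
#' @export
bonded_energy_params <- function(bonds = NULL, angles = NULL, dihedrals = NULL) {
  chk <- function(df, cols, nm) {
    if (is.null(df)) return(NULL)
    if (!all(cols %in% names(df)))
      stop(nm, " needs columns: ", paste(cols, collapse = ", "), call. = FALSE)
    df
  }
  bonds <- chk(bonds, c("index", "kb", "req"), "bonds")
  angles <- chk(angles, c("index", "kphi", "phieq"), "angles")
  dihedrals <- chk(dihedrals, c("index", "vn", "n", "gamma"), "dihedrals")
  if (!is.null(bonds) && any(bonds$kb < 0))
    stop("bond force constants must be >= 0", call. = FALSE)
  if (!is.null(angles) && any(angles$kphi < 0))
    stop("angle force constants must be >= 0", call. = FALSE)
  if (!is.null(dihedrals) &&
      any(abs(dihedrals$gamma) > 1e-12 & abs(dihedrals$gamma - pi) > 1e-12))
    stop("dihedral phase gamma must be 0 or pi", call. = FALSE)
  structure(list(bonds = bonds, angles = angles, dihedrals = dihedrals),
            class = "bonded_energy_params")
}

#' Frame geometry for bonded-energy evaluation
#'
#' Extracts one frame's bond lengths, planar angles and dihedral angles
#' from a trajectory, in the index conventions of
#' [bonded_energy_params()].
#'
#' @param traj a [calpha_trajectory()].
#' @param frame frame index.
#' @return list with `bond_lengths`, `angles`, `dihedrals`.
#' @export
frame_geometry <- function(traj, frame = 1) {
  stopifnot(inherits(traj, "calpha_trajectory"))
  x <- traj$coords[frame, , ]
  nb <- nrow(x)
  bl <- sqrt(rowSums((x[-1, , drop = FALSE] - x[-nb, , drop = FALSE])^2))
  ang <- backbone_angles(calpha_trajectory(array(x, c(1, nb, 3))))
  list(bond_lengths = bl, angles = as.numeric(ang$phi),
       dihedrals = as.numeric(ang$psi))
}

#' Bonded energy components of one frame
#'
#' Evaluates the bonded terms of an AMBER-style potential on one frame's
#' geometry: \eqn{E = \sum k_b (r - r_{eq})^2 + \sum k_\phi (\phi -
#' \phi_{eq})^2 + \sum (V_n/2)(1 + \cos(n\psi - \gamma))}, returning the
#' three components and their sum.
#'
#' @param geometry list as returned by [frame_geometry()].
#' @param params a [bonded_energy_params()].
#' @return list with `bond`, `angle`, `dihedral`, `total` (units follow
#'   the force constants).
#' @export
bonded_energy <- function(geometry, params) {
  stopifnot(inherits(params, "bonded_energy_params"))
  term <- function(df, values, f, what) {
    if (is.null(df) || nrow(df) == 0) return(0)
    if (any(df$index < 1) || any(df$index > length(values)))
      stop("parameterized ", what, " term indexes a nonexistent element",
           call. = FALSE)
    sum(f(values[df$index], df))
  }
  e_bond <- term(params$bonds, geometry$bond_lengths,
                 function(r, df) df$kb * (r - df$req)^2, "bond")
  e_angle <- term(params$angles, geometry$angles,
                  function(a, df) df$kphi * (a - df$phieq)^2, "angle")
  e_dih <- term(params$dihedrals, geometry$dihedrals,
                function(p, df) df$vn / 2 * (1 + cos(df$n * p - df$gamma)),
                "dihedral")
  list(bond = e_bond, angle = e_angle, dihedral = e_dih,
       total = e_bond + e_angle + e_dih)
}
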