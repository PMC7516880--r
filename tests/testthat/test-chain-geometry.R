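test_that("end-to-end vector is last bead minus first and equals the bond-vector sum", {
  tr <- traj_from_frame(straight_chain(11))
  e <- end_to_end_series(tr)
  expect_equal(e$norms, 38.0)
  expect_equal(e$vectors[1, ], c(38, 0, 0))

  set.seed(31)
  m <- matrix(rnorm(50 * 3), ncol = 3)
  e2 <- end_to_end_series(traj_from_frame(m))
  bond_sum <- colSums(m[-1, ] - m[-50, ])     # brute-force sum of tau_j
  expect_equal(as.numeric(e2$vectors[1, ]), bond_sum, tolerance = 1e-12)
  expect_equal(e2$norms[1], sqrt(sum(bond_sum^2)), tolerance = 1e-12)
})

test_that("RMS end-to-end matches hand values and rejects empty windows", {
  co <- array(0, dim = c(2, 4, 3))
  co[1, 4, 1] <- 3; co[2, 4, 1] <- 4          # |R| = 3 then 4
  e <- end_to_end_series(calpha_trajectory(co))
  expect_equal(rms_end_to_end(e), sqrt(12.5))
  expect_equal(rms_end_to_end(e, 1), 3)
  expect_error(rms_end_to_end(e, integer(0)), "empty")
})

test_that("size exponent reproduces the published albumin table at 4 decimals", {
  ref <- albumin_reference()
  joined <- merge(ref$rms_end_to_end, ref$size_exponent,
                  by = c("window", "temperature"))
  expect_equal(nrow(joined), 10)
  mu_hat <- vapply(joined$r_rms,
                   function(r) flory_exponent(r, 3.8, 576)$mu, numeric(1))
  expect_equal(round(mu_hat, 4), joined$mu)
})

test_that("size exponent identities and inversion hold", {
  expect_equal(flory_exponent(3.8 * sqrt(576), 3.8, 576)$mu, 0.5)
  expect_equal(flory_exponent(3.8, 3.8, 576)$mu, 0)
  est <- flory_exponent(47.88, 3.8, 576)
  expect_equal(est$tau * est$n_bonds^est$mu, est$r_rms, tolerance = 1e-12)
  expect_error(flory_exponent(-1, 3.8, 10), "positive")
})

test_that("RMSD alignment conventions behave as specified", {
  base <- straight_chain(9)
  co <- array(0, dim = c(2, 9, 3))
  co[1, , ] <- base
  co[2, , ] <- base + matrix(c(1, 2, 2), 9, 3, byrow = TRUE)
  tr <- calpha_trajectory(co)
  expect_equal(rmsd_series(tr, reference = 1, alignment = "none"),
               c(0, 3.0))
  expect_equal(rmsd_series(tr, reference = 1, alignment = "centroid"),
               c(0, 0), tolerance = 1e-12)

  co2 <- array(0, dim = c(2, 9, 3))
  co2[1, , ] <- base; co2[2, , ] <- base
  co2[2, 5, 2] <- 1.7                          # one bead displaced by d
  tr2 <- calpha_trajectory(co2)
  expect_equal(rmsd_series(tr2, reference = 1, alignment = "none")[2],
               1.7 / sqrt(9))
})

test_that("superposed RMSD is invariant under rigid motion and matches bio3d", {
  set.seed(17)
  co <- array(rnorm(4 * 12 * 3, sd = 3), dim = c(4, 12, 3))
  tr <- calpha_trajectory(co)
  r1 <- rmsd_series(tr, reference = 1, alignment = "centroid+rotation")
  r2 <- rmsd_series(apply_rigid(tr, seed = 99), reference = 1,
                    alignment = "centroid+rotation")
  expect_equal(r1, r2, tolerance = 1e-8)

  ref_xyz <- as.numeric(t(co[1, , ]))
  frame_xyz <- as.numeric(t(co[3, , ]))
  oracle <- bio3d::rmsd(ref_xyz, frame_xyz, fit = TRUE)
  expect_equal(r1[3], oracle, tolerance = 1e-4)
})

test_that("backbone angles match hand geometry and the cross-product oracle", {
  m <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  ang <- backbone_angles(traj_from_frame(m))
  expect_equal(as.numeric(ang$phi), c(pi / 2, pi / 2))
  expect_equal(as.numeric(ang$psi), 0)         # planar cis quadruple

  m_anti <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  expect_equal(abs(as.numeric(backbone_angles(traj_from_frame(m_anti))$psi)),
               pi)

  coll <- straight_chain(4, 1)
  expect_equal(as.numeric(backbone_angles(traj_from_frame(coll))$phi),
               c(pi, pi))

  set.seed(23)
  for (i in 1:20) {
    m4 <- matrix(rnorm(12), 4, 3)
    got <- as.numeric(backbone_angles(traj_from_frame(m4))$psi)
    expect_equal(got, oracle_dihedral(m4[1, ], m4[2, ], m4[3, ], m4[4, ]),
                 tolerance = 1e-10)
  }
})

test_that("backbone angles are invariant under rigid motion and flag degeneracy", {
  set.seed(29)
  co <- array(rnorm(3 * 10 * 3), dim = c(3, 10, 3))
  tr <- calpha_trajectory(co)
  a1 <- backbone_angles(tr)
  a2 <- backbone_angles(apply_rigid(tr, seed = 7))
  expect_equal(a1$phi, a2$phi, tolerance = 1e-8)
  expect_equal(a1$psi, a2$psi, tolerance = 1e-8)

  m <- straight_chain(5)
  m[3, ] <- m[2, ]                             # coincident consecutive beads
  ang <- backbone_angles(traj_from_frame(m))
  expect_true(any(is.na(ang$phi)))
  expect_true(any(is.na(ang$psi)))
})

test_that("bonded energy components evaluate the parameterized terms", {
  geo <- list(bond_lengths = rep(1.5, 5), angles = rep(pi / 2, 4),
              dihedrals = rep(0, 3))
  params0 <- bonded_energy_params(
    bonds = data.frame(index = 1:5, kb = 100, req = 1.5),
    angles = data.frame(index = 1:4, kphi = 50, phieq = pi / 2),
    dihedrals = data.frame(index = 1:3, vn = 2, n = 1, gamma = pi))
  e0 <- bonded_energy(geo, params0)
  # r = req, phi = phieq, cos(psi - pi) = -1 for psi = 0 -> every term zero
  expect_equal(e0$total, 0, tolerance = 1e-10)

  e1 <- bonded_energy(geo, bonded_energy_params(
    dihedrals = data.frame(index = 1, vn = 4, n = 1, gamma = 0)))
  expect_equal(e1$dihedral, 4)                 # cos(psi - 0) = 1 contributes Vn

  geo2 <- list(bond_lengths = 1.6, angles = numeric(0), dihedrals = numeric(0))
  e2 <- bonded_energy(geo2, bonded_energy_params(
    bonds = data.frame(index = 1, kb = 100, req = 1.5)))
  expect_equal(e2$bond, 1.0, tolerance = 1e-12)

  expect_error(bonded_energy(geo, bonded_energy_params(
    bonds = data.frame(index = 99, kb = 1, req = 1))), "nonexistent")
  expect_error(bonded_energy_params(
    dihedrals = data.frame(index = 1, vn = 1, n = 1, gamma = 1)), "gamma")
})

test_that("frame geometry extracts bond lengths and angles consistently", {
  cfg <- ensemble_config(temperatures = "300K", replicas_per_temperature = 1,
                         n_residues = 10, n_frames = 1,
                         chain_model = "rigid_helix_noise",
                         model_params = list(noise_sd = 0), seed = 1)
  tr <- generate_chain_trajectory(cfg, "300K", 1)
  geo <- frame_geometry(tr)
  expect_length(geo$bond_lengths, 9)
  expect_equal(geo$bond_lengths, rep(3.8, 9), tolerance = 1e-9)
  ang <- backbone_angles(tr)
  expect_equal(geo$angles, as.numeric(ang$phi))
  expect_equal(geo$dihedrals, as.numeric(ang$psi))
})

test_that("rms end-to-end is invariant under rigid motion", {
  set.seed(41)
  co <- array(rnorm(5 * 20 * 3, sd = 2), dim = c(5, 20, 3))
  tr <- calpha_trajectory(co)
  expect_equal(rms_end_to_end(end_to_end_series(tr)),
               rms_end_to_end(end_to_end_series(apply_rigid(tr, seed = 3))),
               tolerance = 1e-8)
})
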