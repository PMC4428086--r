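# The independent reference value for mu_w at the canonical settings
# (a = 2.8 A, C_dip = 55 M, T = 300 K) was computed from the closed form
# with 50-digit arithmetic:
#   lambda = N_A*C_dip*a^3 = 0.72708918679936
#   mu_w/kBT = ln(1-lambda)/lambda = -1.7860398040874628
MU_W_REF_KT <- -1.7860398040874628
LAMBDA_REF <- 0.72708918679936

test_that("mu_w matches the high-precision closed form and its limits", {
  cfg <- solver_config()
  expect_equal(fibrilforge:::packing_fraction(cfg), LAMBDA_REF,
               tolerance = 1e-12)
  kT <- 0.0019872041 * 300
  expect_equal(chemical_potential_mu_w(cfg) / kT, MU_W_REF_KT,
               tolerance = 1e-12)
  expect_equal(chemical_potential_mu_w(cfg), -1.065, tolerance = 1e-3)
  # C_dip -> 0 limit: -kBT
  expect_equal(chemical_potential_mu_w(solver_config(C_dip = 0)), -kT,
               tolerance = 1e-12)
  expect_equal(chemical_potential_mu_w(solver_config(C_dip = 1e-9)), -kT,
               tolerance = 1e-6)
  # denser lattice packs tighter and is more negative
  cfg29 <- solver_config(a = 2.9)
  expect_gte(fibrilforge:::packing_fraction(cfg29), 0.80)
  expect_lt(chemical_potential_mu_w(cfg29), chemical_potential_mu_w(cfg))
  # over-close-packed solvent is rejected
  expect_error(chemical_potential_mu_w(solver_config(a = 3.2)),
               "over close-packed")
})

test_that("charge projection is trilinear and conservative", {
  cfg <- solver_config(grid_points = 33L)
  # a charge exactly on a node: all charge on that node
  s <- make_atom_fixture(charge = 1, position = c(0, 0, 0))
  g <- build_grid(s, cfg)
  expect_equal(max(g$q), 1, tolerance = 1e-12)
  expect_equal(sum(g$q != 0), 1L)
  # at a cell centre: 1/8 on each of 8 nodes (the grid is centred on the
  # centroid, so a second uncharged atom offsets the charge mid-cell)
  s2 <- make_particles_fixture(rbind(c(0, 0, 0), c(1, 1, 1)),
                               charge = c(1, 0), radius = 1.7)
  g2 <- build_grid(s2, cfg)
  expect_equal(sort(g2$q[g2$q != 0]), rep(1 / 8, 8), tolerance = 1e-12)
  expect_equal(sum(g2$q), 1, tolerance = 1e-10)
  # charge conservation for a charged multi-atom solute
  s3 <- assign_parameters(fibrilforge:::build_peptide("GRK", rep(-120, 3),
                                                      rep(120, 3)))
  g3 <- build_grid(s3, solver_config(grid_points = 65L))
  expect_equal(sum(g3$q), net_charge(s3), tolerance = 1e-10)
  expect_equal(net_charge(s3), 2, tolerance = 1e-9)
  # solute too large for the grid
  expect_error(build_grid(assign_parameters(make_amylin_monomer_fixture()),
                          solver_config(grid_points = 33L)),
               "increase grid_points")
})

test_that("trivial and vacuum solutions behave", {
  cfg <- solver_config(grid_points = 33L)
  g <- build_grid(NULL, cfg)
  sol <- solve_dpbl(g, cfg)
  expect_true(sol$converged)
  expect_lte(sol$residual, cfg$residual_tol)
  expect_equal(max(abs(sol$phi)), 0)
  rho <- sol$rho_dip[sol$rho_dip > 0]
  expect_equal(max(rho), min(rho))  # uniform bulk
  expect_equal(max(rho), LAMBDA_REF / 2.8^3, tolerance = 1e-9)
  # lattice-gas bound 0 <= rho <= 1/a^3
  expect_true(all(sol$rho_dip >= 0 & sol$rho_dip <= 1 / 2.8^3 + 1e-12))
})

test_that("a vacuum point-charge solution follows Coulomb differences", {
  cfg <- solver_config(grid_points = 65L, p0 = 0, C_dip = 0)
  s <- make_atom_fixture(charge = 1, position = c(0, 0, 0), radius = 2)
  sol <- solve_dpbl(build_grid(s, cfg), cfg)
  n <- cfg$grid_points; mid <- (n + 1) / 2
  at <- function(i, j, k) sol$phi[i + n * (j - 1) + n * n * (k - 1)]
  lB <- 332.0636 / (0.0019872041 * 300)
  # potential differences on-axis remove the boundary offset
  d_num <- at(mid + 5, mid, mid) - at(mid + 10, mid, mid)
  d_ana <- lB * (1 / 5 - 1 / 10)
  expect_equal(d_num, d_ana, tolerance = 0.05 * abs(d_ana))
  # spherical symmetry: the six axis neighbours at distance 5 agree
  vals <- c(at(mid + 5, mid, mid), at(mid - 5, mid, mid),
            at(mid, mid + 5, mid), at(mid, mid - 5, mid),
            at(mid, mid, mid + 5), at(mid, mid, mid - 5))
  expect_lt(diff(range(vals)) / abs(mean(vals)), 1e-6)
})

test_that("dipole count matches the closed-form bulk value", {
  cfg <- solver_config(grid_points = 33L)
  g <- solve_dpbl(build_grid(NULL, cfg), cfg)
  V <- (cfg$grid_points - 2)^3 * cfg$spacing^3  # interior nodes
  expect_equal(dipole_count_Nw(g), LAMBDA_REF / 2.8^3 * V,
               tolerance = 1e-6 * LAMBDA_REF / 2.8^3 * V)
  expect_gte(dipole_count_Nw(g), 0)
  unsolved <- build_grid(NULL, cfg)
  expect_error(dipole_count_Nw(unsolved), "not solved")
})

test_that("empty solute has zero solvation free energy", {
  cfg <- solver_config(grid_points = 65L)
  r <- solvation_free_energy(NULL, cfg)
  expect_true(r$converged)
  expect_lt(abs(r$F_solv), 1e-3)
})

test_that("solvation is quadratic in charge (linear response) and negative", {
  cfg <- solver_config(grid_points = 65L)
  ion <- function(q) make_atom_fixture(charge = q, radius = 2)
  f1 <- solvation_free_energy(ion(0.05), cfg)
  f2 <- solvation_free_energy(ion(0.10), cfg)
  expect_true(f1$converged && f2$converged)
  expect_lt(f1$F_solv, 0)
  expect_equal(f2$F_solv / f1$F_solv, 4, tolerance = 0.05 * 4)
})

test_that("solvation free energy is rotation invariant on a rigid solute", {
  cfg <- solver_config(grid_points = 65L)
  xyz <- rbind(c(-2, 0, 0), c(2, 0, 0), c(0, 2.5, 0))
  mk <- function(m) make_particles_fixture(m, radius = 1.9,
                                           charge = c(0.4, -0.4, 0.3))
  f0 <- solvation_free_energy(mk(xyz), cfg)$F_solv
  R <- fibrilforge:::rotation_about_axis(c(1, 1, 1), 2 * pi / 5)
  f1 <- solvation_free_energy(mk(xyz %*% t(R)), cfg)$F_solv
  expect_equal(f1, f0, tolerance = 0.02 * abs(f0))
})

test_that("grid refinement changes a toy ion energy by less than 10%", {
  ion <- make_atom_fixture(charge = 1, radius = 2)
  f1 <- solvation_free_energy(ion, solver_config(grid_points = 65L))$F_solv
  f05 <- solvation_free_energy(ion, solver_config(grid_points = 129L,
                                                  spacing = 0.5))$F_solv
  expect_equal(f05, f1, tolerance = 0.10 * abs(f1))
})
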