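test_that("energy model construction follows the contact rules", {
  fr <- make_two_bead_dimer(0.6)
  m <- build_energy_model(fr, contact_cutoff = 0.8)
  expect_equal(nrow(m$contacts), 1L)
  expect_equal(unname(m$contacts[1, "sigma"]), 0.6, tolerance = 1e-12)
  expect_equal(unname(m$contacts[1, "inter"]), 1)
  expect_equal(nrow(m$bonds), 0L)

  lad <- make_ladder_dimer(6, sep = 0.55)
  ml <- build_energy_model(lad, contact_cutoff = 0.8)
  # intra contacts exclude |i - j| <= 2
  intra <- ml$contacts[ml$contacts[, "inter"] == 0, , drop = FALSE]
  if (nrow(intra))
    expect_true(all(abs(intra[, "i"] - intra[, "j"]) > 2))
  expect_equal(nrow(ml$bonds), 10L)  # 5 per chain
  expect_error(build_energy_model(make_helix_frame(5)), "two-chain")
  expect_warning(build_energy_model(make_ladder_dimer(4, sep = 3)),
                 "no inter-chain")
})

test_that("native conformation is an energy minimum of the Go model", {
  lad <- make_ladder_dimer(8)
  m <- build_energy_model(lad, epsilon_intra = 1, epsilon_inter = 2)
  e0 <- go_energy(m, m$coords)
  set.seed(10)
  for (k in 1:100) {
    pert <- m$coords + matrix(rnorm(length(m$coords), 0, 0.03),
                              nrow(m$coords))
    expect_gte(go_energy(m, pert), e0)
  }
})

test_that("total energy reproduces the virtual-spring closed form", {
  fr <- make_two_bead_dimer(0.5)
  m <- build_energy_model(fr, contact_cutoff = 0.8, epsilon_inter = 2)
  # at t = 0 and L = L0 the spring term vanishes
  p0 <- pulling_protocol(k = 35, v_nm_per_sweep = 1e-4, L0 = 0.5)
  expect_equal(total_energy(m, fr, p0, t = 0), go_energy(m, m$coords))
  # hand computation: k = 10 pN/nm, L - L0 - v t = 0.5 nm
  # spring energy = 0.5 * 10 * 0.25 = 1.25 pN nm = 1.25 / kT kT
  p1 <- pulling_protocol(k = 10, v_nm_per_sweep = 0, L0 = 0.0)
  got <- total_energy(m, fr, p1, t = 0)
  expect_equal(got - go_energy(m, m$coords), 1.25 / kT_pN_nm(300),
               tolerance = 1e-12)
  # k -> 0 limit: spring term vanishes for all t
  p2 <- pulling_protocol(k = 1e-12, v_nm_per_sweep = 1, L0 = 0.5)
  expect_equal(total_energy(m, fr, p2, t = 1000), go_energy(m, m$coords),
               tolerance = 1e-6)
})

test_that("velocity mapping is a pure unit conversion", {
  vm <- velocity_mapping(0.083, 500)
  expect_equal(vm$v_nm_per_step, 8.3e-8)
  expect_equal(vm$steps_per_second, 500 / 8.3e-8)
  # per-sweep speed = per-step speed x mobile beads
  fr <- make_two_bead_dimer(0.5)
  m <- build_energy_model(fr, epsilon_inter = 1)
  p <- pulling_protocol(v_fm_per_step = 0.083, max_sweeps = 10L,
                        record_stride = 1L, tune = FALSE, seed = 1)
  res <- run_pulling(fr, m, p)
  expect_equal(res$v_nm_per_sweep, 0.083e-6 * 2)
})

test_that("pulling runs are seeded, reproducible, and self-consistent", {
  lad <- make_ladder_dimer(6)
  m <- build_energy_model(lad, epsilon_inter = 2)
  p <- pulling_protocol(k = 35, v_nm_per_sweep = 1e-3, max_sweeps = 20000L,
                        record_stride = 10L, seed = 99, move_sigma = 0.02)
  r1 <- run_pulling(lad, m, p)
  r2 <- run_pulling(lad, m, p)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$rupture_force, r2$rupture_force)
  # trace force recomputation: force = k (L - L0 - v t), t = sweep - 1
  expected <- p$k * (r1$trace$L - r1$L0 - r1$v_nm_per_sweep *
                       (r1$trace$sweep - 1))
  expect_equal(r1$trace$force_pN, expected, tolerance = 1e-9)
})

test_that("v = 0 with anchors at L0 stays bound and unruptured", {
  fr <- make_two_bead_dimer(0.5)
  m <- build_energy_model(fr, contact_cutoff = 0.8, epsilon_inter = 20)
  p <- pulling_protocol(k = 35, v_nm_per_sweep = 0, max_sweeps = 20000L,
                        record_stride = 10L, seed = 3, move_sigma = 0.01)
  res <- run_pulling(fr, m, p)
  expect_false(res$ruptured)
  kT <- kT_pN_nm(300)
  width <- sqrt(kT / 35)
  expect_lt(abs(mean(res$trace$L) - 0.5), 3 * width)
})

test_that("zero inter-chain attraction ruptures below the noise scale", {
  fr <- make_two_bead_dimer(0.5)
  m <- suppressWarnings(
    build_energy_model(fr, contact_cutoff = 0.8, epsilon_inter = 0))
  thresh <- 3 * sqrt(35 * kT_pN_nm(300))
  fs <- vapply(1:10, function(s) {
    p <- pulling_protocol(k = 35, v_nm_per_sweep = 1e-4, max_sweeps = 50000L,
                          dwell = 50L, seed = s, move_sigma = 0.05)
    run_pulling(fr, m, p)$rupture_force
  }, numeric(1))
  expect_lt(mean(fs), thresh)
})

test_that("single-contact rupture approaches the max-slope oracle", {
  # deterministic-limit regime: deep well, finite ramp (module-level quick
  # check; the full 100-seed version runs in the acceptance suite)
  fr <- make_two_bead_dimer(0.5)
  eps <- 150
  m <- build_energy_model(fr, contact_cutoff = 0.8, epsilon_inter = eps)
  fstar <- bf_max_contact_force(eps, 0.5) * kT_pN_nm(300)
  fs <- vapply(1:15, function(s) {
    p <- pulling_protocol(k = 35, v_nm_per_sweep = 2e-3, max_sweeps = 2e6,
                          dwell = 200L, seed = s, move_sigma = 0.01)
    run_pulling(fr, m, p)$rupture_force
  }, numeric(1))
  expect_lt(abs(mean(fs) - fstar) / fstar, 0.25)
})

test_that("mean rupture force is non-decreasing in inter-chain epsilon", {
  lad <- make_ladder_dimer(10)
  means <- vapply(c(1, 2, 4), function(eps) {
    m <- build_energy_model(lad, epsilon_intra = 1, epsilon_inter = eps)
    mean(vapply(1:20, function(s) {
      p <- pulling_protocol(k = 35, v_nm_per_sweep = 5e-4,
                            max_sweeps = 300000L, seed = 500 + s,
                            move_sigma = 0.02)
      run_pulling(lad, m, p)$rupture_force
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("pull_ensemble aggregates runs with metadata", {
  lad <- make_ladder_dimer(6)
  p <- pulling_protocol(k = 35, v_nm_per_sweep = 2e-3, max_sweeps = 50000L,
                        seed = 7, move_sigma = 0.02)
  ds <- pull_ensemble(ensemble(list(lad)), p, n_runs_per_conf = 5,
                      epsilon_inter = 2)
  runs <- attr(ds, "runs")
  expect_equal(nrow(runs), 5L)
  expect_lte(length(ds), 5L)
  expect_true(all(ds$forces >= 0))
  # normalized output via contour length
  ds2 <- pull_ensemble(ensemble(list(lad)), p, n_runs_per_conf = 5,
                       contour_length = default_contour_length(10),
                       epsilon_inter = 2)
  expect_true(ds2$normalized)
})

test_that("strong and weak dimers are statistically distinguishable", {
  lad <- make_ladder_dimer(8)
  p <- pulling_protocol(k = 35, v_nm_per_sweep = 1e-3, max_sweeps = 1e5,
                        seed = 17, move_sigma = 0.02)
  weak <- pull_ensemble(ensemble(list(lad)), p, n_runs_per_conf = 40,
                        epsilon_inter = 1)
  strong <- pull_ensemble(ensemble(list(lad)), p, n_runs_per_conf = 40,
                          epsilon_inter = 4)
  cmp <- ks_compare(weak$forces, strong$forces, alpha = 0.05)
  expect_false(cmp$similar)
  # duplicated conformation at the same epsilon is indistinguishable
  p2 <- p; p2$seed <- 1234
  again <- pull_ensemble(ensemble(list(lad)), p2, n_runs_per_conf = 40,
                         epsilon_inter = 1)
  cmp2 <- ks_compare(weak$forces, again$forces, alpha = 0.05)
  expect_true(cmp2$similar)
})
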