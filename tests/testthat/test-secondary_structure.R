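test_that("dihedral computation matches canonical geometry", {
  # cis -> 0, trans -> 180
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(abs(dihedral_angle(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                                  c(1, 0, 0))), 180)
  # ideal helix rebuilt from dihedrals returns them
  dh <- compute_dihedrals(ensemble(list(make_helix_frame(10))))
  expect_lt(max(abs(dh$phi[1, -1] + 57)), 2)
  expect_lt(max(abs(dh$psi[1, -10] + 47)), 2)
  # termini undefined, never imputed
  expect_true(is.na(dh$phi[1, 1]))
  expect_true(is.na(dh$psi[1, 10]))
  dh2 <- compute_dihedrals(ensemble(list(build_backbone(c(NA, -60), c(120, NA)))))
  expect_identical(is.na(dh2$phi[1, ]), c(TRUE, FALSE))
  expect_identical(is.na(dh2$psi[1, ]), c(FALSE, TRUE))
})

test_that("pair-rule assignment follows the criterion boxes", {
  mk <- function(phi3, psi3, phi4, psi4) {
    phi <- matrix(c(NA, -170, phi3, phi4, 10), 1)
    psi <- matrix(c(170, 10, psi3, psi4, NA), 1)
    dihedral_series(phi, psi)
  }
  lab <- function(s) assign_dihedral_ss(s)$labels[1, ]
  expect_identical(lab(mk(-60, -40, -60, -40))[3:4], c("alpha", "alpha"))
  expect_identical(lab(mk(-120, 120, -120, 120))[3:4], c("beta", "beta"))
  # mixed pair agrees with neither box jointly -> coil
  expect_identical(lab(mk(-60, -40, -120, 120))[3:4], c("coil", "coil"))
  # inclusive boundaries
  expect_identical(lab(mk(-80, -59, -48, -27))[3:4], c("alpha", "alpha"))
  expect_identical(lab(mk(-150, 90, -90, 150))[3:4], c("beta", "beta"))
  # just outside
  expect_identical(lab(mk(-80.01, -59, -48, -27))[3:4], c("coil", "coil"))
  # "first" rule marks only the leading residue
  s <- mk(-60, -40, -60, -40)
  expect_identical(assign_dihedral_ss(s, pair_rule = "first")$labels[1, 3:4],
                   c("alpha", "coil"))
})

test_that("assignment equals the brute-force pair scan on random input", {
  set.seed(99)
  Tn <- 200L; R <- 6L
  phi <- matrix(runif(Tn * R, -180, 180), Tn, R)
  psi <- matrix(runif(Tn * R, -180, 180), Tn, R)
  # concentrate mass near the boxes so hits actually occur
  sel <- sample(length(phi), length(phi) / 2)
  phi[sel] <- runif(length(sel), -160, -40)
  psi[sel] <- sample(c(runif(length(sel) / 2, -70, -20),
                       runif(length(sel) - length(sel) / 2, 80, 160)))
  ss <- assign_dihedral_ss(dihedral_series(phi, psi))
  expect_identical(ss$labels, bf_pair_labels(phi, psi))
  # exclusivity invariant
  expect_false(any(ss$delta_alpha & ss$delta_beta))
})

test_that("chain boundaries never form pairs", {
  phi <- matrix(rep(-60, 4), 1); psi <- matrix(rep(-40, 4), 1)
  s <- dihedral_series(phi, psi, chain_id = c("A", "A", "B", "B"))
  lab <- assign_dihedral_ss(s)$labels[1, ]
  expect_identical(lab, c("alpha", "alpha", "alpha", "alpha"))
  s2 <- dihedral_series(phi, psi, chain_id = c("A", "B", "B", "B"))
  # residue 1 alone in chain A has no pair partner
  expect_identical(assign_dihedral_ss(s2)$labels[1, 1], "coil")
})

test_that("windowed fractions behave like indicator means", {
  prof <- propensity_profile(8, p_alpha = 1)
  e <- sample_dihedral_chain(prof, 10, seed = 1, frame_dt = 0.5)
  ss <- assign_dihedral_ss(compute_dihedrals(e))
  ts <- ss_fraction_timeseries(ss, window = 1)
  # 6 of 8 residues can be labeled (termini excluded) -> constant 0.75
  expect_true(all(abs(ts$frac_alpha - 0.75) < 1e-12))
  expect_true(all(ts$frac_beta == 0))
  expect_error(ss_fraction_timeseries(ss, window = 0.1), "frame spacing")

  # alternating all-alpha / all-coil frames average to half per window
  phi <- matrix(rep(c(-60, 100), each = 4, times = 10), 20, 4, byrow = TRUE)
  psi <- matrix(rep(c(-40, 100), each = 4, times = 10), 20, 4, byrow = TRUE)
  ssa <- assign_dihedral_ss(dihedral_series(phi, psi,
                                            times = 0.25 * (1:20)))
  ts2 <- ss_fraction_timeseries(ssa, window = 0.5)
  expect_true(all(abs(ts2$frac_alpha - 0.5) < 1e-12))

  # concatenation invariance: global mean = frame-weighted window mean
  expect_equal(sum(ts2$frac_alpha * ts2$n_frames) / sum(ts2$n_frames),
               mean(ssa$delta_alpha))
})

test_that("binomial label rates are recovered in long windows", {
  set.seed(123)
  Tn <- 4000L; R <- 10L
  # direct i.i.d. labels via box membership with P(alpha pair chain) ~ p
  lab <- matrix(runif(Tn * R) < 0.3, Tn, R)
  phi <- ifelse(lab, -60, 100); psi <- ifelse(lab, -40, 100)
  # force pair structure: duplicate columns so pairs always agree
  phi <- phi[, rep(1:5, each = 2)]; psi <- psi[, rep(1:5, each = 2)]
  ss <- assign_dihedral_ss(dihedral_series(phi, psi,
                                           times = seq_len(Tn) * 0.01))
  ts <- ss_fraction_timeseries(ss, window = 40)
  se <- sd(rowMeans(ss$delta_alpha)) / sqrt(Tn)
  expect_lt(abs(mean(ts$frac_alpha) - 0.3), 3 * se)
})

test_that("hydrogen-bond assignment matches the reference DSSP fixtures", {
  expect_identical(assign_hbond_ss(make_helix_frame(12)),
                   helix12_oracle_labels)
  # fully extended chain: no H-bonds at all
  ext <- build_backbone(rep(-180, 10), rep(180, 10))
  expect_true(all(assign_hbond_ss(ext) == "C"))
  # antiparallel two-strand sheet: frozen labels from the reference DSSP
  expect_identical(assign_hbond_ss(make_beta_sheet_frame()),
                   sheet_oracle_labels)
})

test_that("per-residue probabilities are well-formed and chain-resolved", {
  f <- make_helix_frame(12)
  tab <- ss_probability_per_residue(ensemble(list(f)), method = "hbond")
  expect_true(all(abs(rowSums(tab[, c("p_H", "p_E", "p_C")]) - 1) < 1e-12))
  expect_true(all(tab$p_H[3:10] == 1))

  # two chains with different propensity profiles differ accordingly
  profA <- propensity_profile(10, p_alpha = 0.9)
  profB <- propensity_profile(10, p_beta = 0.9)
  spec <- dimer_spec(profA, profB, NULL)
  e <- build_dimer(spec, 60, seed = 44, min_separation = 0)
  tab2 <- ss_probability_per_residue(e, method = "dihedral")
  a <- tab2[tab2$chain == "A", ]; b <- tab2[tab2$chain == "B", ]
  expect_gt(mean(a$p_alpha[3:8]), mean(b$p_alpha[3:8]) + 0.3)
  expect_gt(mean(b$p_beta[3:8]), mean(a$p_beta[3:8]) + 0.3)
  # oracle check for chain A interior
  exp_a <- bf_alpha_label_prob(0.9, 10)
  expect_lt(max(abs(a$p_alpha[4:7] - exp_a[4:7])), 3 * sqrt(0.25 / 60) + 0.02)
  # dual residue numbering is exposed
  expect_identical(tab2$residue_peptide, tab2$residue - 1L)
})
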