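test_that("superposition is exact for rigid motions", {
  f <- make_helix_frame(8)
  expect_equal(superpose(f, f)$rmsd, 0, tolerance = 1e-12)
  R <- .rotmat_axis(c(0.3, -1.2, 0.7))
  g <- f
  g$coords <- sweep(f$coords %*% t(R), 2, c(1, -2, 0.5), "+")
  fit <- superpose(g, f)
  expect_lt(fit$rmsd, 1e-6)
  expect_lt(max(abs(fit$frame$coords - f$coords)), 1e-6)
})

test_that("superposition matches a rotation-grid oracle on 4-atom toys", {
  set.seed(5)
  mk4 <- function(co) structure_frame(co, rep("CA", 4), 1:4, "ALA", "A")
  P <- matrix(rnorm(12), 4, 3)
  Q <- matrix(rnorm(12), 4, 3)
  got <- superpose(mk4(P), mk4(Q), atoms = "CA")$rmsd
  # oracle: coarse axis-angle grid then local refinement, centered inputs
  P0 <- sweep(P, 2, colMeans(P)); Q0 <- sweep(Q, 2, colMeans(Q))
  obj <- function(w) sqrt(mean(rowSums((P0 %*% t(.rotmat_axis(w)) - Q0)^2)))
  best <- Inf
  for (ax in seq(-pi, pi, length.out = 7)) for (ay in seq(-pi, pi, length.out = 7))
    for (az in seq(-pi, pi, length.out = 7)) {
      o <- optim(c(ax, ay, az), obj, control = list(maxit = 500, reltol = 1e-14))
      best <- min(best, o$value)
    }
  expect_lt(abs(got - best), 1e-4)
  expect_lte(got, best + 1e-9)  # Kabsch is the true optimum
})

test_that("rmsd matrix is symmetric, zero-diagonal, and consistent", {
  prof <- propensity_profile(6, p_alpha = 0.5, p_beta = 0.3)
  e <- sample_dihedral_chain(prof, 5, seed = 77)
  e$frames[[4]] <- e$frames[[2]]  # duplicate
  M <- rmsd_matrix(e)
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
  expect_lt(M[2, 4], 1e-10)
  for (i in 1:4) for (j in (i + 1):5) {
    direct <- superpose(e$frames[[i]], e$frames[[j]],
                        atoms = c("N", "CA", "C", "O"))$rmsd
    expect_equal(M[i, j], direct, tolerance = 1e-9)
  }
})

test_that("gromos clustering handles the degenerate regimes", {
  M <- matrix(0.1, 4, 4); diag(M) <- 0
  cl <- gromos_cluster(M, 0.45)
  expect_equal(length(cl$populations), 1L)
  expect_equal(cl$populations, 1)
  expect_true(all(cl$assignments == 1L))

  M2 <- matrix(5, 4, 4); diag(M2) <- 0
  cl2 <- gromos_cluster(M2, 0.45)
  expect_equal(length(cl2$populations), 4L)
  expect_equal(sort(cl2$representatives), 1:4)
  expect_error(gromos_cluster(matrix(NA_real_, 2, 2), 0.45), "NA")
})

test_that("gromos clustering equals the brute-force greedy oracle", {
  # hand-built 7-frame matrix with two overlapping neighborhoods
  d <- matrix(1, 7, 7); diag(d) <- 0
  set_d <- function(i, j, v) { d[i, j] <<- v; d[j, i] <<- v }
  set_d(1, 2, 0.2); set_d(1, 3, 0.3); set_d(2, 3, 0.4)
  set_d(3, 4, 0.4); set_d(4, 5, 0.2); set_d(5, 6, 0.3); set_d(4, 6, 0.44)
  got <- gromos_cluster(d, 0.45)
  ora <- bf_gromos(d, 0.45)
  expect_identical(got$assignments, ora$assignments)
  expect_identical(got$representatives, ora$representatives)
  expect_equal(got$populations, ora$populations)
  expect_equal(sum(got$populations), 1)

  set.seed(42)
  for (rep in 1:10) {
    n <- 12L
    x <- matrix(runif(n * n, 0, 1), n, n)
    M <- (x + t(x)) / 2; diag(M) <- 0
    g <- gromos_cluster(M, 0.4); o <- bf_gromos(M, 0.4)
    expect_identical(g$assignments, o$assignments)
    expect_equal(g$populations, o$populations)
  }
})

test_that("contact maps are indicator means with exact pooling", {
  f <- make_two_bead_dimer(0.5)
  e <- ensemble(list(f))
  cm <- contact_probability_map(e, c("A", "B"), cutoff = 0.8)
  expect_equal(cm$matrix[1, 1], 1)
  far <- make_two_bead_dimer(5)
  expect_equal(contact_probability_map(ensemble(list(far)), c("A", "B"),
                                       cutoff = 0.8)$matrix[1, 1], 0)
  # pooling: concatenated map = frame-weighted mean (exact)
  e2 <- ensemble(list(f, far, far))
  cm2 <- contact_probability_map(e2, c("A", "B"), cutoff = 0.8)
  expect_identical(cm2$matrix[1, 1], 1 / 3)
  expect_error(contact_probability_map(e, c("A", "Z")), "not present")
})

test_that("intra maps are symmetric and difference maps signed", {
  prof <- propensity_profile(8, p_alpha = 0.7)
  e <- sample_dihedral_chain(prof, 10, seed = 3)
  A <- contact_probability_map(e, c("A", "A"), cutoff = 0.8)
  expect_equal(A$matrix, t(A$matrix))
  expect_true(all(A$matrix >= 0 & A$matrix <= 1))
  dd <- contact_difference(A, A)
  expect_true(all(dd$matrix == 0))
  expect_identical(dd$mode, "difference")
  B <- A; B$matrix <- matrix(0, 8, 8)
  d2 <- contact_difference(A, B)
  expect_identical(d2$matrix, A$matrix)
  inter <- contact_probability_map(
    ensemble(list(make_two_bead_dimer())), c("A", "B"))
  expect_error(contact_difference(inter, inter), "intra")
  # near-diagonal masking flag
  Am <- contact_probability_map(e, c("A", "A"), cutoff = 0.8,
                                mask_neighbors = TRUE)
  expect_true(all(is.na(diag(Am$matrix))))
})

test_that("shape descriptors match closed forms", {
  f2 <- structure_frame(rbind(c(0, 0, 0), c(1, 0, 0)), c("CA", "CA"),
                        1:2, "ALA", "A")
  expect_equal(shape_descriptors(f2)$radius_of_gyration, 0.5)
  # single sphere: SASA = 4 pi (r + w)^2 within 2%
  f1 <- structure_frame(matrix(0, 1, 3), "CA", 1L, "ALA", "A")
  expect_equal(sasa_shrake_rupley(f1, probe_radius = 0.14, sphere_points = 960),
               4 * pi * (0.17 + 0.14)^2, tolerance = 0.02)
  # unit cube of 8 atoms -> hull volume 1
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convex_hull_volume(cube), 1, tolerance = 1e-12)
  expect_error(convex_hull_volume(cube[1:3, ]), "at least 4")
  expect_error(convex_hull_volume(cbind(runif(10), runif(10), 0)),
               "degenerate")
})

test_that("hull volume matches the brute-force facet oracle", {
  set.seed(8)
  for (rep in 1:5) {
    pts <- matrix(rnorm(3 * 15), ncol = 3)
    expect_equal(convex_hull_volume(pts), bf_hull_volume(pts),
                 tolerance = 1e-9)
  }
  # interior points must not change the hull
  pts <- matrix(rnorm(30), ncol = 3)
  withmid <- rbind(pts, colMeans(pts))
  expect_equal(convex_hull_volume(withmid), convex_hull_volume(pts),
               tolerance = 1e-12)
})

test_that("two-conformer ensembles produce bimodal RMSD structure", {
  pa <- propensity_profile(8, p_alpha = 1)
  pb <- propensity_profile(8, p_beta = 1)
  ea <- sample_dihedral_chain(pa, 6, seed = 1)
  eb <- sample_dihedral_chain(pb, 6, seed = 1)
  eb$frames <- lapply(eb$frames, function(f) {
    f$residue_name <- ea$frames[[1]]$residue_name; f })
  e <- concat_ensembles(ea, eb)
  M <- rmsd_matrix(e)
  within <- c(M[1:6, 1:6][upper.tri(M[1:6, 1:6])],
              M[7:12, 7:12][upper.tri(M[7:12, 7:12])])
  across <- as.vector(M[1:6, 7:12])
  expect_gt(min(across), max(within))
  cl <- gromos_cluster(M, cutoff = max(within) + 1e-6)
  expect_equal(length(cl$populations), 2L)
})
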