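# Ensemble-level analyses: pairwise RMSD, GROMOS clustering, contact
# probability maps, and geometric shape descriptors.

#' Progressive fit of a trajectory (de-drifting)
#'
#' Fits each frame onto the previous fitted frame, mirroring trjconv-style
#' progressive fitting. Optional pre-step before clustering; clustering
#' itself always uses pairwise minimal RMSD and is unaffected.
#'
#' @param ens an [ensemble()].
#' @param atoms fit selection.
#' @return the fitted ensemble.
#' @export
progressive_fit <- function(ens, atoms = c("N", "CA", "C")) {
  out <- ens
  for (i in seq_len(n_frames(ens))[-1]) {
    out$frames[[i]] <- superpose(out$frames[[i]], out$frames[[i - 1]],
                                 atoms = atoms)$frame
  }
  out
}

#' Pairwise minimal-RMSD matrix of an ensemble
#'
#' Entry (i, j) is the RMSD (nm) of frames i and j after optimal
#' superposition on the selected atoms. Symmetric, zero diagonal.
#'
#' @param ens an [ensemble()] with >= 2 frames.
#' @param atoms atom-name selection (default backbone N/CA/C/O).
#' @return symmetric numeric matrix (nm).
#' @export
rmsd_matrix <- function(ens, atoms = c("N", "CA", "C", "O")) {
  Tn <- n_frames(ens)
  if (Tn < 2L) stop("need at least 2 frames")
  mask <- atom_mask(ens$frames[[1]], atoms = atoms)
  if (!any(mask)) stop("empty atom selection")
  sel <- lapply(ens$frames, function(f) f$coords[mask, , drop = FALSE])
  cen <- lapply(sel, function(P) sweep(P, 2, colMeans(P)))
  ss <- vapply(cen, function(P) sum(P * P), numeric(1))
  n <- nrow(cen[[1]])
  M <- matrix(0, Tn, Tn)
  for (i in seq_len(Tn - 1)) {
    Pi <- cen[[i]]
    for (j in (i + 1):Tn) {
      H <- crossprod(Pi, cen[[j]])
      sv <- svd(H)$d
      # Kabsch RMSD via singular values with chirality correction
      d <- sign(det(crossprod(Pi, cen[[j]])))
      if (d < 0) sv[3] <- -sv[3]
      msd <- max((ss[i] + ss[j] - 2 * sum(sv)) / n, 0)
      M[i, j] <- M[j, i] <- sqrt(msd)
    }
  }
  M
}

#' GROMOS neighbor-count clustering of an RMSD matrix
#'
#' Iteratively selects the frame with the most neighbors within `cutoff`
#' as a cluster center, assigns it and all its neighbors to the cluster,
#' removes them, and repeats. Ties in neighbor count are broken by the
#' lowest frame index. Clusters are ordered by descending population
#' (ties: lower center index first).
#'
#' @param rmsd square symmetric RMSD matrix (nm), no NAs.
#' @param cutoff neighbor cutoff (nm), default 0.45 (= 4.5 Angstrom).
#' @return object of class `cluster_result`: `assignments` (frame ->
#'   cluster id, 1 = most populated), `representatives` (center frame per
#'   cluster), `populations` (fractions summing to 1), `cutoff`.
#' @export
gromos_cluster <- function(rmsd, cutoff = 0.45) {
  rmsd <- as.matrix(rmsd)
  if (nrow(rmsd) != ncol(rmsd)) stop("rmsd must be square")
  if (any(is.na(rmsd))) stop("NA entries in rmsd matrix")
  if (cutoff <= 0) stop("cutoff must be > 0")
  Tn <- nrow(rmsd)
  adj <- rmsd <= cutoff
  diag(adj) <- TRUE
  alive <- rep(TRUE, Tn)
  centers <- integer(0); members <- list()
  while (any(alive)) {
    cnt <- colSums(adj & alive) * alive  # neighbor counts among surviving
    center <- which.max(cnt)             # which.max -> lowest index on ties
    neigh <- which(adj[, center] & alive)
    centers <- c(centers, center)
    members[[length(members) + 1L]] <- neigh
    alive[neigh] <- FALSE
  }
  pop <- vapply(members, length, integer(1)) / Tn
  ord <- order(-pop, centers)
  assignments <- integer(Tn)
  for (k in seq_along(ord)) assignments[members[[ord[k]]]] <- k
  structure(list(assignments = assignments,
                 representatives = centers[ord],
                 populations = pop[ord], cutoff = cutoff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d clusters (cutoff %.3g nm); top populations: %s\n",
              length(x$populations), x$cutoff,
              paste(sprintf("%.1f%%", 100 * head(x$populations, 5)),
                    collapse = ", ")))
  invisible(x)
}

#' C-alpha contact probability map
#'
#' Entry (i, j) is the fraction of frames in which the CA-CA distance of
#' residue i (first chain of `chain_pair`) and residue j (second chain)
#' is at most `cutoff`. Intra-chain maps (both chains equal) are
#' symmetric; `mask_neighbors` blanks trivially contacting near-diagonal
#' pairs (|i - j| <= 2) with NA for reporting.
#'
#' @param ens an [ensemble()].
#' @param chain_pair length-2 character vector of chain ids, e.g.
#'   `c("A", "A")` (intra) or `c("A", "B")` (inter).
#' @param cutoff contact cutoff in nm (default 0.8).
#' @param mask_neighbors mask |i - j| <= 2 in intra maps.
#' @return object of class `contact_map`: `matrix` (probabilities),
#'   `mode` ("intra"/"inter"), `cutoff`, residue index annotations.
#' @export
contact_probability_map <- function(ens, chain_pair = c("A", "B"),
                                    cutoff = 0.8, mask_neighbors = FALSE) {
  stopifnot(length(chain_pair) == 2L)
  f1 <- ens$frames[[1]]
  if (!all(chain_pair %in% chain_ids(f1)))
    stop("requested chain(s) not present")
  mi <- atom_mask(f1, atoms = "CA", chain = chain_pair[1])
  mj <- atom_mask(f1, atoms = "CA", chain = chain_pair[2])
  if (!any(mi) || !any(mj)) stop("missing CA atoms for requested chains")
  acc <- matrix(0, sum(mi), sum(mj))
  for (f in ens$frames) {
    A <- f$coords[mi, , drop = FALSE]; B <- f$coords[mj, , drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    acc <- acc + (d2 <= cutoff^2)
  }
  P <- acc / n_frames(ens)
  mode <- if (chain_pair[1] == chain_pair[2]) "intra" else "inter"
  if (mode == "intra" && mask_neighbors) {
    ij <- abs(outer(seq_len(nrow(P)), seq_len(ncol(P)), "-"))
    P[ij <= 2] <- NA_real_
  }
  structure(list(matrix = P, mode = mode, cutoff = cutoff,
                 residue_i = f1$residue_index[mi],
                 residue_j = f1$residue_index[mj],
                 chain_pair = chain_pair),
            class = "contact_map")
}

#' Difference of two intra-chain contact maps
#'
#' Element-wise `map_a - map_b` (sign convention: first minus second
#' monomer). Entries lie in `[-1, 1]`.
#'
#' @param map_a,map_b `contact_map`s of equal shape, both intra.
#' @return a `contact_map` with `mode = "difference"`.
#' @export
contact_difference <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "contact_map"), inherits(map_b, "contact_map"))
  if (map_a$mode != "intra" || map_b$mode != "intra")
    stop("difference maps are defined for intra maps")
  if (!all(dim(map_a$matrix) == dim(map_b$matrix)))
    stop("contact map shapes differ")
  out <- map_a
  out$matrix <- map_a$matrix - map_b$matrix
  out$mode <- "difference"
  out
}

# van der Waals radii (nm) keyed by element; Bondi-style published values
.vdw_radii <- c(C = 0.170, N = 0.155, O = 0.152, S = 0.180, H = 0.120)
.atom_masses <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008)

.sphere_points <- function(m) {
  # deterministic golden-spiral points on the unit sphere
  i <- seq_len(m) - 0.5
  phi <- acos(1 - 2 * i / m)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent accessible surface area
#'
#' @param frame a [structure_frame()].
#' @param probe_radius probe radius in nm (default 0.14, water).
#' @param sphere_points test points per atom (default 960).
#' @return SASA in nm^2.
#' @export
sasa_shrake_rupley <- function(frame, probe_radius = 0.14,
                               sphere_points = 960L) {
  el <- .guess_element(frame$atom_name)
  r <- unname(.vdw_radii[el]) + probe_radius
  co <- frame$coords
  n <- nrow(co)
  pts <- .sphere_points(sphere_points)
  total <- 0
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(co, 2, co[i, ])^2)
    neigh <- which(d2 < (r[i] + r)^2 & seq_len(n) != i)
    surf <- sweep(pts * r[i], 2, co[i, ], "+")
    acc <- rep(TRUE, sphere_points)
    for (j in neigh) {
      dj <- rowSums(sweep(surf, 2, co[j, ])^2)
      acc <- acc & dj > r[j]^2
      if (!any(acc)) break
    }
    total <- total + 4 * pi * r[i]^2 * mean(acc)
  }
  total
}

#' Geometric shape descriptors of a frame
#'
#' Mass-weighted radius of gyration, convex-hull volume of the atom
#' centers, and Shrake-Rupley SASA.
#'
#' @param frame a [structure_frame()].
#' @param probe_radius SASA probe radius (nm).
#' @param sphere_points SASA test points per atom.
#' @return list with `radius_of_gyration` (nm), `volume` (nm^3),
#'   `sasa` (nm^2).
#' @export
shape_descriptors <- function(frame, probe_radius = 0.14,
                              sphere_points = 960L) {
  el <- .guess_element(frame$atom_name)
  m <- unname(.atom_masses[el])
  co <- frame$coords
  com <- colSums(co * m) / sum(m)
  rg <- sqrt(sum(m * rowSums(sweep(co, 2, com)^2)) / sum(m))
  # hull volume undefined below 4 non-coplanar atoms; reported as NA
  vol <- if (nrow(co) >= 4L)
    tryCatch(convex_hull_volume(co), error = function(e) NA_real_)
  else NA_real_
  list(radius_of_gyration = rg, volume = vol,
       sasa = sasa_shrake_rupley(frame, probe_radius, sphere_points))
}

#' Convex hull volume of a 3D point set
#'
#' @param points n x 3 matrix (n >= 4, not all coplanar).
#' @return volume in the cube of the coordinate unit.
#' @export
convex_hull_volume <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4L) stop("need at least 4 points for a 3D hull")
  v <- hull_volume_cpp(points)
  if (v < 0) stop("degenerate (coplanar) point set")
  v
}
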