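# Dihedral principal component analysis and free-energy landscapes.

.dpca_features <- function(dh) {
  # residues with both phi and psi defined in every frame
  ok <- colSums(is.na(dh$phi)) == 0L & colSums(is.na(dh$psi)) == 0L
  idx <- which(ok)
  if (!length(idx)) stop("no residues with complete dihedrals")
  phir <- dh$phi[, idx, drop = FALSE] * pi / 180
  psir <- dh$psi[, idx, drop = FALSE] * pi / 180
  X <- cbind(cos(phir), sin(phir), cos(psir), sin(psir))
  colnames(X) <- c(paste0("cos_phi_", idx), paste0("sin_phi_", idx),
                   paste0("cos_psi_", idx), paste0("sin_psi_", idx))
  list(X = X, residues = idx)
}

#' Fit a dihedral PCA model
#'
#' PCA on the mean-centered per-residue features
#' (cos phi, sin phi, cos psi, sin psi), the established dPCA convention
#' that removes angular periodicity artifacts. Component signs are fixed
#' by making the largest-magnitude loading of each component positive.
#'
#' @param ens an [ensemble()] (>= 2 frames) or a `dihedral_series`.
#' @return object of class `dpca_model`: `center`, `rotation`
#'   (orthonormal columns), `variances` (non-increasing), `residues`
#'   (feature residues), `topology_hash`.
#' @export
fit_dpca <- function(ens) {
  dh <- if (inherits(ens, "dihedral_series")) ens else compute_dihedrals(ens)
  if (nrow(dh$phi) < 2L) stop("need at least 2 frames")
  ft <- .dpca_features(dh)
  pc <- prcomp(ft$X, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  for (k in seq_len(ncol(rot))) {
    w <- which.max(abs(rot[, k]))
    if (rot[w, k] < 0) rot[, k] <- -rot[, k]
  }
  structure(list(center = pc$center, rotation = rot,
                 variances = pc$sdev^2, residues = ft$residues,
                 topology_hash = if (inherits(ens, "ensemble"))
                   ens$topology_hash else NA_character_),
            class = "dpca_model")
}

#' Project an ensemble onto a dPCA model
#'
#' @param model a `dpca_model`.
#' @param ens an [ensemble()] or `dihedral_series` with the same topology
#'   as the training data.
#' @param n_components number of components to return (default 2).
#' @return frames x n_components matrix of scores.
#' @export
project_dpca <- function(model, ens, n_components = 2L) {
  dh <- if (inherits(ens, "dihedral_series")) ens else compute_dihedrals(ens)
  ft <- .dpca_features(dh)
  if (!identical(ft$residues, model$residues))
    stop("topology mismatch between model and ensemble")
  Z <- sweep(ft$X, 2, model$center) %*%
    model$rotation[, seq_len(n_components), drop = FALSE]
  colnames(Z) <- paste0("PC", seq_len(n_components))
  Z
}

#' Free-energy landscape over the first two dPCA components
#'
#' 2D histogram of projections; per-bin free energy
#' `dG = -ln(count / max count)` in kT units, so the modal bin is 0 and
#' empty bins are `Inf` (missing, never interpolated). Minima are basins
#' found by persistence (union-find over occupied bins in increasing dG):
#' a basin survives as a separate minimum when its persistence (merge
#' level minus basin minimum) is at least `min_depth` and its center is
#' at least `min_separation` bins (Chebyshev) from any deeper kept
#' minimum.
#'
#' @param proj frames x >=2 projection matrix (see [project_dpca()]).
#' @param bins bins per axis (default 64).
#' @param min_depth minimum basin persistence in kT (default 0.5).
#' @param min_separation minimum separation between minima in bins.
#' @param min_count minimum bin occupancy for minima candidacy (default 5).
#'   Below this the Poisson error of `-ln(count)` exceeds any sensible
#'   depth threshold (count 1 vs 2 already differs by ln 2 = 0.69 kT), so
#'   sparser bins are shown in the landscape but never reported as minima.
#' @return object of class `energy_landscape`: `grid_x`, `grid_y` (bin
#'   centers), `counts`, `dG` matrix, and `minima` data.frame (bin
#'   indices, PC coordinates, dG, representative frame index).
#' @export
energy_landscape <- function(proj, bins = 64L, min_depth = 0.5,
                             min_separation = 2L, min_count = 5L) {
  proj <- as.matrix(proj)
  if (nrow(proj) < 1L) stop("need at least one projection")
  if (bins < 2L) stop("need at least 2 bins per axis")
  x <- proj[, 1]; y <- proj[, 2]
  pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else
    r + c(-1, 1) * 1e-9 * max(abs(r), 1)
  rx <- pad(range(x)); ry <- pad(range(y))
  bx <- seq(rx[1], rx[2], length.out = bins + 1L)
  by <- seq(ry[1], ry[2], length.out = bins + 1L)
  ix <- pmin(pmax(findInterval(x, bx, rightmost.closed = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(y, by, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0L, bins, bins)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  dG <- -log(counts / max(counts))
  dG[counts == 0L] <- Inf
  dml <- dG
  dml[counts < min_count] <- Inf
  if (!any(is.finite(dml))) dml <- dG   # tiny samples: fall back to raw
  minima <- .find_minima(dml, min_depth, min_separation)
  cx <- (bx[-1] + bx[-length(bx)]) / 2
  cy <- (by[-1] + by[-length(by)]) / 2
  if (nrow(minima)) {
    minima$PC1 <- cx[minima$bin_x]; minima$PC2 <- cy[minima$bin_y]
    minima$frame <- vapply(seq_len(nrow(minima)), function(r) {
      which.min((x - minima$PC1[r])^2 + (y - minima$PC2[r])^2)
    }, integer(1))
  }
  structure(list(grid_x = cx, grid_y = cy, counts = counts, dG = dG,
                 minima = minima, n_frames = nrow(proj)),
            class = "energy_landscape")
}

# persistence-based minima detection on a dG grid (Inf = empty)
.find_minima <- function(dG, min_depth, min_separation) {
  nb <- nrow(dG); occ <- which(is.finite(dG))
  if (!length(occ)) return(data.frame())
  ord <- occ[order(dG[occ])]
  parent <- integer(length(dG))          # 0 = unprocessed
  basin_min <- numeric(length(dG))       # dG at basin minimum (at root)
  basin_seed <- integer(length(dG))      # linear index of basin minimum
  persistence <- setNames(numeric(0), character(0))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  dead <- c()
  for (lin in ord) {
    r <- (lin - 1L) %% nb + 1L; c <- (lin - 1L) %/% nb + 1L
    neigh <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nb && cc >= 1 && cc <= ncol(dG)) {
        nl <- rr + (cc - 1L) * nb
        if (parent[nl] != 0L) neigh <- c(neigh, nl)
      }
    }
    if (!length(neigh)) {               # new basin
      parent[lin] <- lin; basin_min[lin] <- dG[lin]; basin_seed[lin] <- lin
      next
    }
    roots <- unique(vapply(neigh, find, integer(1)))
    main <- roots[which.min(basin_min[roots])]
    parent[lin] <- main
    for (rt in setdiff(roots, main)) {  # merge younger basins at level dG[lin]
      pers <- dG[lin] - basin_min[rt]
      if (pers < min_depth) {
        dead <- c(dead, basin_seed[rt])
      } else {
        persistence[as.character(basin_seed[rt])] <- pers
      }
      parent[rt] <- main
    }
  }
  # surviving roots get persistence up to the landscape cap
  cap <- max(dG[occ])
  roots <- unique(vapply(occ, find, integer(1)))
  for (rt in roots) {
    s <- basin_seed[rt]
    if (!(s %in% dead) && !(as.character(s) %in% names(persistence)))
      persistence[as.character(s)] <- cap - basin_min[rt]
  }
  keep <- as.integer(names(persistence))[persistence >= min_depth]
  if (!length(keep)) keep <- occ[which.min(dG[occ])]  # global minimum always
  keep <- keep[order(dG[keep])]
  sel <- integer(0)
  for (k in keep) {
    kr <- (k - 1L) %% nb + 1L; kc <- (k - 1L) %/% nb + 1L
    ok <- TRUE
    for (s in sel) {
      sr <- (s - 1L) %% nb + 1L; sc <- (s - 1L) %/% nb + 1L
      if (max(abs(kr - sr), abs(kc - sc)) < min_separation) { ok <- FALSE; break }
    }
    if (ok) sel <- c(sel, k)
  }
  data.frame(bin_x = (sel - 1L) %% nb + 1L,
             bin_y = (sel - 1L) %/% nb + 1L,
             dG = dG[sel])
}

#' Pooled dPCA landscape over several ensembles
#'
#' Concatenates the ensembles (shared topology required), refits the dPCA
#' model on the pooled frames, and recomputes the landscape; mirrors the
#' pool-then-refit workflow used for combining trajectory segments.
#'
#' @param ensembles list of [ensemble()]s.
#' @param ... passed to [energy_landscape()].
#' @return list with `model`, `projections`, `landscape`, `ensemble`.
#' @export
pooled_landscape <- function(ensembles, ...) {
  pooled <- concat_ensembles(ensembles)
  model <- fit_dpca(pooled)
  proj <- project_dpca(model, pooled)
  list(model = model, projections = proj,
       landscape = energy_landscape(proj, ...), ensemble = pooled)
}
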