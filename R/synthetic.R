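# Synthetic ground-truth generators: dihedral-propensity chain ensembles,
# restraint-docked dimers, and Gaussian-mixture rupture datasets.

# Dihedral boxes of the secondary-structure criterion (degrees, inclusive)
.alpha_box <- c(phi_lo = -80, phi_hi = -48, psi_lo = -59, psi_hi = -27)
.beta_box  <- c(phi_lo = -150, phi_hi = -90, psi_lo = 90, psi_hi = 150)

#' Per-residue secondary-structure propensity profile
#'
#' States are drawn independently per residue and frame; an "alpha" state
#' residue receives (phi, psi) uniform inside the helix dihedral box, a
#' "beta" state inside the strand box, and "coil" uniform over the
#' complement of both boxes.
#'
#' @param n chain length in residues.
#' @param p_alpha,p_beta per-residue state probabilities, recycled to
#'   length `n`; `p_coil = 1 - p_alpha - p_beta`.
#' @return object of class `propensity_profile`.
#' @export
propensity_profile <- function(n, p_alpha = 0, p_beta = 0) {
  p_alpha <- rep_len(p_alpha, n); p_beta <- rep_len(p_beta, n)
  p_coil <- 1 - p_alpha - p_beta
  if (any(p_alpha < 0 | p_beta < 0 | p_coil < -1e-12))
    stop("propensities must be in [0,1] and sum to at most 1 per residue")
  p_coil <- pmax(p_coil, 0)
  structure(list(n = as.integer(n), p_alpha = p_alpha, p_beta = p_beta,
                 p_coil = p_coil),
            class = "propensity_profile")
}

.sample_box <- function(box, m) {
  cbind(phi = runif(m, box["phi_lo"], box["phi_hi"]),
        psi = runif(m, box["psi_lo"], box["psi_hi"]))
}

.sample_coil <- function(m) {
  # rejection from the full Ramachandran square minus both boxes
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < m) {
    k <- max(2 * (m - nrow(out)), 8)
    phi <- runif(k, -180, 180); psi <- runif(k, -180, 180)
    ina <- phi >= .alpha_box["phi_lo"] & phi <= .alpha_box["phi_hi"] &
      psi >= .alpha_box["psi_lo"] & psi <= .alpha_box["psi_hi"]
    inb <- phi >= .beta_box["phi_lo"] & phi <= .beta_box["phi_hi"] &
      psi >= .beta_box["psi_lo"] & psi <= .beta_box["psi_hi"]
    out <- rbind(out, cbind(phi, psi)[!ina & !inb, , drop = FALSE])
  }
  out[seq_len(m), , drop = FALSE]
}

.clash_count <- function(frame, min_separation) {
  if (min_separation <= 0) return(0L)
  d <- as.matrix(dist(frame$coords))
  # atoms of the same or adjacent residues are closer than any sensible
  # clash threshold even at ideal geometry; exclude them
  near <- abs(outer(frame$residue_index, frame$residue_index, "-")) <= 1L &
    outer(frame$chain_id, frame$chain_id, "==")
  sum(d < min_separation & !near & upper.tri(d))
}

#' Sample a single-chain ensemble from a propensity profile
#'
#' Each frame draws per-residue states from the profile, assigns dihedrals
#' from the corresponding box (coil from the complement), and rebuilds the
#' backbone at ideal geometry. Frames with steric clashes (non-bonded atom
#' pair closer than `min_separation`) are resampled up to `max_retry`
#' times; if retries are exhausted the least-clashing frame is kept with a
#' warning.
#'
#' @param profile a [propensity_profile()].
#' @param n_frames number of frames (>= 1).
#' @param seed RNG seed; identical seeds give bit-identical ensembles.
#' @param chain_id chain identifier.
#' @param residue_name residue codes (default: the package's 41-residue
#'   sequence when `profile$n == 41`, else "ALA").
#' @param min_separation clash threshold in nm (0 disables the check).
#' @param max_retry resampling budget per frame.
#' @param frame_dt frame spacing in ns for the time axis.
#' @return an [ensemble()]; the drawn state matrix (frames x residues,
#'   values "alpha"/"beta"/"coil") is attached as attribute `states`.
#' @export
sample_dihedral_chain <- function(profile, n_frames, seed = 1L,
                                  chain_id = "A", residue_name = NULL,
                                  min_separation = 0.025, max_retry = 50L,
                                  frame_dt = 0.1) {
  stopifnot(inherits(profile, "propensity_profile"), n_frames >= 1)
  n <- profile$n
  if (is.null(residue_name))
    residue_name <- if (n == 41L) ab40_cys_sequence() else "ALA"
  set.seed(as.integer(seed))
  states <- matrix(NA_character_, n_frames, n)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    best <- NULL; best_clash <- Inf
    for (try in seq_len(max_retry)) {
      st <- vapply(seq_len(n), function(i)
        sample(c("alpha", "beta", "coil"), 1L,
               prob = c(profile$p_alpha[i], profile$p_beta[i],
                        profile$p_coil[i])),
        character(1))
      ang <- matrix(NA_real_, n, 2)
      ia <- st == "alpha"; ib <- st == "beta"; ic <- st == "coil"
      if (any(ia)) ang[ia, ] <- .sample_box(.alpha_box, sum(ia))
      if (any(ib)) ang[ib, ] <- .sample_box(.beta_box, sum(ib))
      if (any(ic)) ang[ic, ] <- .sample_coil(sum(ic))
      fr <- build_backbone(ang[, 1], ang[, 2], residue_name, chain_id)
      cl <- .clash_count(fr, min_separation)
      if (cl < best_clash) { best <- list(fr = fr, st = st); best_clash <- cl }
      if (cl == 0L) break
    }
    if (best_clash > 0L)
      warning(sprintf("frame %d kept with %d residual clash(es) after %d retries",
                      f, best_clash, max_retry))
    frames[[f]] <- best$fr
    states[f, ] <- best$st
  }
  e <- ensemble(frames, times = frame_dt * seq_len(n_frames))
  attr(e, "states") <- states
  e
}

#' Dimer generation specification
#'
#' @param profile_a,profile_b [propensity_profile()]s for the two chains.
#' @param inter_contact_pairs integer matrix/data.frame with columns
#'   (residue in chain A, residue in chain B) of target inter-chain
#'   contacts; may be empty.
#' @param contact_distance CA-CA distance (nm) defining a satisfied
#'   contact.
#' @return object of class `dimer_spec`.
#' @export
dimer_spec <- function(profile_a, profile_b, inter_contact_pairs = NULL,
                       contact_distance = 0.8) {
  if (contact_distance <= 0) stop("contact_distance must be > 0")
  if (is.null(inter_contact_pairs)) {
    pairs <- matrix(integer(0), 0, 2)
  } else {
    pairs <- as.matrix(inter_contact_pairs)
    if (ncol(pairs) != 2L) stop("inter_contact_pairs needs two columns")
    storage.mode(pairs) <- "integer"
    if (any(pairs[, 1] < 1 | pairs[, 1] > profile_a$n) ||
        any(pairs[, 2] < 1 | pairs[, 2] > profile_b$n))
      stop("contact pair references an invalid residue")
  }
  structure(list(profile_a = profile_a, profile_b = profile_b,
                 pairs = pairs, contact_distance = contact_distance),
            class = "dimer_spec")
}

.merge_frames <- function(fa, fb) {
  structure_frame(rbind(fa$coords, fb$coords),
                  c(fa$atom_name, fb$atom_name),
                  c(fa$residue_index, fb$residue_index),
                  c(fa$residue_name, fb$residue_name),
                  c(fa$chain_id, fb$chain_id))
}

.dock_pair <- function(fa, fb, pairs, contact_distance, n_orient = 120L,
                       min_sep_empty = 2) {
  ca_a <- ca_coords(fa); ca_b0 <- ca_coords(fb)
  if (nrow(pairs) == 0L) {
    # place chain B beyond min_sep_empty of chain A along x
    shift <- c(max(fa$coords[, 1]) - min(fb$coords[, 1]) + min_sep_empty, 0, 0)
    fb$coords <- sweep(fb$coords, 2, shift, "+")
    return(list(frame = .merge_frames(fa, fb), score = 0, ok = TRUE))
  }
  target_a <- ca_a[pairs[, 1], , drop = FALSE]
  best <- NULL
  for (k in seq_len(n_orient)) {
    R <- .rand_rotation()
    cb <- ca_b0 %*% t(R)
    # translate so that the contact-residue centroids coincide, then back
    # off along the centroid gap direction to the target contact distance
    src <- cb[pairs[, 2], , drop = FALSE]
    tr <- colMeans(target_a) - colMeans(src)
    jit <- rnorm(3, 0, 0.05 * contact_distance)
    cb2 <- sweep(cb, 2, tr + jit, "+")
    dd <- sqrt(rowSums((target_a - cb2[pairs[, 2], , drop = FALSE])^2))
    sat <- mean(dd <= contact_distance)
    # clash: any inter-chain CA pair too close
    d2 <- outer(rowSums(ca_a^2), rowSums(cb2^2), "+") - 2 * ca_a %*% t(cb2)
    dmin <- sqrt(max(min(d2), 0))
    score <- sat - ifelse(dmin < 0.35, 2 * (0.35 - dmin), 0)
    if (is.null(best) || score > best$score) {
      best <- list(R = R, tr = tr + jit, score = score, sat = sat)
      if (sat == 1 && dmin >= 0.35) break
    }
  }
  fb$coords <- sweep(fb$coords %*% t(best$R), 2, best$tr, "+")
  list(frame = .merge_frames(fa, fb), score = best$score,
       ok = best$sat == 1)
}

#' Generate a docked two-chain dimer ensemble
#'
#' Both chains are sampled with [sample_dihedral_chain()]; for each frame
#' chain B is rigid-body docked onto chain A by best-of-K random
#' orientations scored on satisfaction of the requested inter-chain
#' contacts plus a clash penalty. With an empty contact list the chains
#' are separated by at least 2 nm.
#'
#' @param spec a [dimer_spec()].
#' @param n_frames frames to generate.
#' @param seed RNG seed (bit-identical output for identical seeds).
#' @param max_retry docking retries per frame before giving up.
#' @param ... passed to [sample_dihedral_chain()] (e.g. `min_separation`).
#' @return an [ensemble()] of two-chain frames (chains "A" and "B").
#' @export
build_dimer <- function(spec, n_frames, seed = 1L, max_retry = 8L, ...) {
  stopifnot(inherits(spec, "dimer_spec"))
  ea <- sample_dihedral_chain(spec$profile_a, n_frames, seed = seed,
                              chain_id = "A", ...)
  eb <- sample_dihedral_chain(spec$profile_b, n_frames, seed = seed + 1L,
                              chain_id = "B", ...)
  set.seed(as.integer(seed) + 2L)
  frames <- vector("list", n_frames)
  n_fail <- 0L
  for (f in seq_len(n_frames)) {
    res <- NULL
    for (r in seq_len(max_retry)) {
      res <- .dock_pair(ea$frames[[f]], eb$frames[[f]], spec$pairs,
                        spec$contact_distance)
      if (res$ok) break
    }
    if (!res$ok) n_fail <- n_fail + 1L
    frames[[f]] <- res$frame
  }
  if (nrow(spec$pairs) && n_fail > 0.5 * n_frames)
    stop("infeasible contact set: docking failed in ", n_fail, " of ",
         n_frames, " frames")
  ensemble(frames, times = ea$times)
}

#' Sample a rupture dataset from a Gaussian mixture
#'
#' Draws `n` i.i.d. (force, position) pairs from a mixture of bivariate
#' independent Gaussians. Forces are truncated at 0 (rejection);
#' normalized positions are truncated to `[0, 1]`.
#'
#' @param components data.frame/matrix with columns `weight`, `mean_force`
#'   (pN), `sd_force`, `mean_pos`, `sd_pos`; weights must sum to 1.
#' @param n sample size (0 gives an empty dataset).
#' @param seed RNG seed.
#' @param normalized logical; whether positions are on the normalized
#'   `[0, 1]` scale.
#' @param label dataset label.
#' @return a [rupture_dataset()].
#' @export
sample_rupture_data <- function(components, n, seed = 1L, normalized = TRUE,
                                label = "synthetic") {
  cm <- as.data.frame(components)
  need <- c("weight", "mean_force", "sd_force", "mean_pos", "sd_pos")
  if (!all(need %in% names(cm))) {
    if (ncol(cm) == 5L) names(cm) <- need else
      stop("components needs columns ", paste(need, collapse = ", "))
  }
  if (abs(sum(cm$weight) - 1) > 1e-8) stop("weights must sum to 1")
  if (any(cm$sd_force <= 0 | cm$sd_pos <= 0)) stop("sds must be > 0")
  set.seed(as.integer(seed))
  if (n == 0L)
    return(rupture_dataset(numeric(0), numeric(0), label, normalized))
  comp <- sample.int(nrow(cm), n, replace = TRUE, prob = cm$weight)
  draw_trunc <- function(mu, sg, lo, hi) {
    x <- rnorm(length(mu), mu, sg)
    bad <- which(x < lo | x > hi)
    while (length(bad)) {
      x[bad] <- rnorm(length(bad), mu[bad], sg[bad])
      bad <- bad[x[bad] < lo | x[bad] > hi]
    }
    x
  }
  f <- draw_trunc(cm$mean_force[comp], cm$sd_force[comp], 0, Inf)
  p <- if (normalized)
    draw_trunc(cm$mean_pos[comp], cm$sd_pos[comp], 0, 1)
  else draw_trunc(cm$mean_pos[comp], cm$sd_pos[comp], 0, Inf)
  ds <- rupture_dataset(f, p, label, normalized)
  ds$component <- comp
  ds
}
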