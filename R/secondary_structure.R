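# Secondary structure from backbone dihedrals (consecutive-pair criterion)
# and from backbone hydrogen bonds (reduced DSSP-like assigner).

#' Compute per-frame backbone dihedrals of an ensemble
#'
#' Standard IUPAC phi/psi per chain. phi is undefined (NA) for the first
#' residue of each chain, psi for the last; terminal values are never
#' imputed.
#'
#' @param ens an [ensemble()] whose frames carry N, CA, C atoms.
#' @return object of class `dihedral_series`: list with `phi` and `psi`
#'   (frames x residues matrices, degrees), `residue_index`, `chain_id`
#'   (per residue), and `times`.
#' @export
compute_dihedrals <- function(ens) {
  stopifnot(inherits(ens, "ensemble"))
  f1 <- ens$frames[[1]]
  need <- c("N", "CA", "C")
  idx <- lapply(need, function(a) which(f1$atom_name == a))
  names(idx) <- need
  res_chain <- f1$chain_id[idx$CA]
  res_index <- f1$residue_index[idx$CA]
  nres <- length(idx$CA)
  if (length(idx$N) != nres || length(idx$C) != nres)
    stop("backbone N/CA/C atoms must be present once per residue")
  Tn <- n_frames(ens)
  phi <- psi <- matrix(NA_real_, Tn, nres)
  same_chain_next <- c(res_chain[-1] == res_chain[-nres], FALSE)
  for (t in seq_len(Tn)) {
    co <- ens$frames[[t]]$coords
    N <- co[idx$N, , drop = FALSE]
    CA <- co[idx$CA, , drop = FALSE]
    C <- co[idx$C, , drop = FALSE]
    i <- which(c(FALSE, same_chain_next[-nres]))  # residues with a predecessor
    if (length(i))
      phi[t, i] <- dihedral_angle(C[i - 1, , drop = FALSE],
                                  N[i, , drop = FALSE],
                                  CA[i, , drop = FALSE],
                                  C[i, , drop = FALSE])
    j <- which(same_chain_next)                   # residues with a successor
    if (length(j))
      psi[t, j] <- dihedral_angle(N[j, , drop = FALSE],
                                  CA[j, , drop = FALSE],
                                  C[j, , drop = FALSE],
                                  N[j + 1, , drop = FALSE])
  }
  structure(list(phi = phi, psi = psi, residue_index = res_index,
                 chain_id = res_chain, times = ens$times),
            class = "dihedral_series")
}

#' Construct a dihedral series from raw angle matrices
#'
#' Convenience constructor for tests and oracle comparisons that bypass
#' geometry.
#'
#' @param phi,psi frames x residues matrices (degrees; NA allowed).
#' @param chain_id per-residue chain ids.
#' @param times optional frame times (ns).
#' @return a `dihedral_series`.
#' @export
dihedral_series <- function(phi, psi, chain_id = NULL, times = NULL) {
  phi <- as.matrix(phi); psi <- as.matrix(psi)
  stopifnot(all(dim(phi) == dim(psi)))
  if (is.null(chain_id)) chain_id <- rep("A", ncol(phi))
  structure(list(phi = phi, psi = psi,
                 residue_index = seq_len(ncol(phi)),
                 chain_id = chain_id, times = times),
            class = "dihedral_series")
}

.in_box <- function(phi, psi, box) {
  !is.na(phi) & !is.na(psi) &
    phi >= box["phi_lo"] & phi <= box["phi_hi"] &
    psi >= box["psi_lo"] & psi <= box["psi_hi"]
}

#' Assign alpha/beta/coil states from the consecutive-pair dihedral rule
#'
#' A pair of consecutive residues (i, i+1) in the same chain is a helix
#' pair when both residues' (phi, psi) lie inside the helix box
#' (-80 <= phi <= -48, -59 <= psi <= -27, bounds inclusive) and a strand
#' pair for the strand box (-150 <= phi <= -90, 90 <= psi <= 150). Under
#' `pair_rule = "both"` (default) each satisfying pair marks both of its
#' residues; `"first"` marks only the leading residue. Everything else is
#' coil. The two boxes are disjoint in phi, so a residue can never be
#' alpha and beta in the same frame.
#'
#' @param dh a `dihedral_series` (see [compute_dihedrals()]).
#' @param pair_rule which residues a satisfying pair marks.
#' @return object of class `ss_matrix`: `labels` (frames x residues,
#'   "alpha"/"beta"/"coil"), indicator matrices `delta_alpha`,
#'   `delta_beta`, plus residue/chain metadata and times.
#' @export
assign_dihedral_ss <- function(dh, pair_rule = c("both", "first")) {
  pair_rule <- match.arg(pair_rule)
  stopifnot(inherits(dh, "dihedral_series"))
  nres <- ncol(dh$phi)
  ina <- .in_box(dh$phi, dh$psi, .alpha_box)
  inb <- .in_box(dh$phi, dh$psi, .beta_box)
  same_next <- dh$chain_id[-nres] == dh$chain_id[-1]
  mark_from_pairs <- function(inbox) {
    lab <- matrix(FALSE, nrow(inbox), nres)
    if (nres >= 2L) {
      pair_ok <- inbox[, -nres, drop = FALSE] & inbox[, -1, drop = FALSE]
      pair_ok <- sweep(pair_ok, 2, same_next, "&")
      lab[, -nres] <- lab[, -nres, drop = FALSE] | pair_ok
      if (pair_rule == "both")
        lab[, -1] <- lab[, -1, drop = FALSE] | pair_ok
    }
    lab
  }
  da <- mark_from_pairs(ina)
  db <- mark_from_pairs(inb)
  labels <- matrix("coil", nrow(da), nres)
  labels[da] <- "alpha"
  labels[db] <- "beta"
  structure(list(labels = labels, delta_alpha = da, delta_beta = db,
                 residue_index = dh$residue_index, chain_id = dh$chain_id,
                 times = dh$times),
            class = "ss_matrix")
}

#' Windowed secondary-structure fraction time series
#'
#' For each time window `[s, s + window)` the fraction is the mean of the
#' per-residue state indicators over all residues and all frames falling
#' in the window.
#'
#' @param ss an `ss_matrix` with frame times.
#' @param window window width Delta in ns (default 1).
#' @param smooth_k optional running-average filter width in windows
#'   (0 = none); the raw series is always returned.
#' @return data.frame with `t` (window start, ns), `frac_alpha`,
#'   `frac_beta`, `n_frames`, and (when `smooth_k > 0`) `frac_alpha_smooth`,
#'   `frac_beta_smooth`.
#' @export
ss_fraction_timeseries <- function(ss, window = 1, smooth_k = 0L) {
  stopifnot(inherits(ss, "ss_matrix"))
  if (is.null(ss$times)) stop("frame times are required")
  if (window <= 0) stop("window must be > 0")
  if (length(ss$times) > 1L && window < min(diff(ss$times)))
    stop("window smaller than the frame spacing")
  t0 <- min(ss$times)
  bin <- floor((ss$times - t0) / window)
  fa <- rowMeans(ss$delta_alpha); fb <- rowMeans(ss$delta_beta)
  agg <- aggregate(cbind(frac_alpha = fa, frac_beta = fb, n_frames = 1),
                   by = list(bin = bin), FUN = sum)
  out <- data.frame(t = t0 + agg$bin * window,
                    frac_alpha = agg$frac_alpha / agg$n_frames,
                    frac_beta = agg$frac_beta / agg$n_frames,
                    n_frames = agg$n_frames)
  if (smooth_k > 0L) {
    out$frac_alpha_smooth <- running_average(out$frac_alpha, smooth_k)
    out$frac_beta_smooth <- running_average(out$frac_beta, smooth_k)
  }
  out
}

#' Centered running average (partial windows at the edges)
#' @param x numeric vector.
#' @param k filter width (windows).
#' @return filtered vector, same length.
#' @export
running_average <- function(x, k = 10L) {
  n <- length(x)
  half <- floor(k / 2)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

# ---- reduced hydrogen-bond (DSSP-like) assignment ----------------------

.place_amide_h <- function(N, C_prev, O_prev) {
  # standard DSSP practice: N-H anti-parallel to the preceding carbonyl C=O
  d <- C_prev - O_prev
  N + 0.101 * d / sqrt(sum(d * d))
}

.hbond_matrix <- function(frame) {
  # Kabsch-Sander electrostatic energy; hb[i, j] = TRUE when the N-H of
  # residue i donates to the C=O of residue j (E < -0.5 kcal/mol)
  ca_idx <- which(frame$atom_name == "CA")
  nres <- length(ca_idx)
  get <- function(a) {
    out <- matrix(NA_real_, nres, 3)
    w <- which(frame$atom_name == a)
    ri <- match(paste(frame$chain_id[w], frame$residue_index[w]),
                paste(frame$chain_id[ca_idx], frame$residue_index[ca_idx]))
    out[ri, ] <- frame$coords[w, , drop = FALSE]
    out
  }
  N <- get("N"); C <- get("C"); O <- get("O")
  if (any(is.na(O))) stop("carbonyl O atoms required for H-bond assignment")
  chain <- frame$chain_id[ca_idx]
  resnm <- frame$residue_name[ca_idx]
  H <- matrix(NA_real_, nres, 3)
  for (i in 2:nres) {
    if (chain[i] == chain[i - 1] && resnm[i] != "PRO")
      H[i, ] <- .place_amide_h(N[i, ], C[i - 1, ], O[i - 1, ])
  }
  hb <- matrix(FALSE, nres, nres)
  q <- 27.888  # 0.084 * 332 kcal/mol * Angstrom
  for (i in seq_len(nres)) {
    if (is.na(H[i, 1])) next
    for (j in seq_len(nres)) {
      if (i == j || abs(i - j) == 1L && chain[i] == chain[j]) next
      rON <- 10 * sqrt(sum((O[j, ] - N[i, ])^2))
      rCH <- 10 * sqrt(sum((C[j, ] - H[i, ])^2))
      rOH <- 10 * sqrt(sum((O[j, ] - H[i, ])^2))
      rCN <- 10 * sqrt(sum((C[j, ] - N[i, ])^2))
      if (min(rON, rOH) < 0.5) { hb[i, j] <- TRUE; next }
      E <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      hb[i, j] <- E < -0.5
    }
  }
  attr(hb, "chain") <- chain
  hb
}

#' Hydrogen-bond secondary-structure labels for one frame
#'
#' Reduced DSSP: backbone H-bonds by the Kabsch-Sander electrostatic
#' criterion (amide H placed at 1.01 Angstrom from N, anti to the previous
#' carbonyl), helix H from two consecutive i -> i+4 turns, strand E from
#' parallel/antiparallel bridge patterns, everything else coil. Helix
#' takes priority over strand, as in DSSP.
#'
#' @param frame a [structure_frame()] with backbone N, CA, C, O atoms.
#' @return character vector of per-residue labels in `c("H", "E", "C")`.
#' @export
assign_hbond_ss <- function(frame) {
  hb <- .hbond_matrix(frame)
  chain <- attr(hb, "chain")
  nres <- nrow(hb)
  lab <- rep("C", nres)
  # 4-turn at i: H-bond from NH(i+4) to CO(i), same chain
  turn4 <- rep(FALSE, nres)
  for (i in seq_len(nres - 4)) {
    if (chain[i] == chain[i + 4] && hb[i + 4, i]) turn4[i] <- TRUE
  }
  is_E <- rep(FALSE, nres)
  for (i in seq_len(nres)) {
    for (j in seq_len(nres)) {
      same <- chain[i] == chain[j]
      if (same && abs(i - j) <= 2L) next
      hbd <- function(a, b) a >= 1 && a <= nres && b >= 1 && b <= nres && hb[a, b]
      par <- (hbd(i - 1, j) && hbd(j, i + 1)) || (hbd(j - 1, i) && hbd(i, j + 1))
      anti <- (hbd(i, j) && hbd(j, i)) || (hbd(i - 1, j + 1) && hbd(j - 1, i + 1))
      if (par || anti) { is_E[i] <- TRUE; is_E[j] <- TRUE }
    }
  }
  lab[is_E] <- "E"
  for (i in seq_len(nres - 1)) {
    if (turn4[i] && i > 1 && turn4[i - 1]) {
      lab[i:min(i + 3, nres)] <- "H"
    }
  }
  lab
}

#' Per-residue secondary-structure probabilities over an ensemble
#'
#' @param ens an [ensemble()].
#' @param method `"dihedral"` (consecutive-pair criterion, classes
#'   alpha/beta/coil) or `"hbond"` (reduced DSSP, classes H/E/C).
#' @param pair_rule passed to [assign_dihedral_ss()].
#' @return data.frame with `chain`, `residue` (internal numbering),
#'   `residue_peptide` (mature-peptide numbering, Cys anchor = 0), and one
#'   probability column per class; probabilities sum to 1 per residue.
#' @export
ss_probability_per_residue <- function(ens, method = c("dihedral", "hbond"),
                                       pair_rule = "both") {
  method <- match.arg(method)
  if (method == "dihedral") {
    ss <- assign_dihedral_ss(compute_dihedrals(ens), pair_rule = pair_rule)
    labs <- ss$labels
    classes <- c("alpha", "beta", "coil")
    chain <- ss$chain_id; res <- ss$residue_index
  } else {
    labs <- t(vapply(ens$frames, assign_hbond_ss,
                     character(length(which(ens$frames[[1]]$atom_name == "CA")))))
    classes <- c("H", "E", "C")
    caw <- which(ens$frames[[1]]$atom_name == "CA")
    chain <- ens$frames[[1]]$chain_id[caw]
    res <- ens$frames[[1]]$residue_index[caw]
  }
  probs <- sapply(classes, function(cl) colMeans(labs == cl))
  out <- data.frame(chain = chain, residue = res,
                    residue_peptide = residue_numbering(res, "peptide"))
  for (cl in classes) out[[paste0("p_", cl)]] <- probs[, cl]
  out
}
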