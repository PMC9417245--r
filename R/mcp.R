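# Monte Carlo pulling: structure-based (Go-type) energy model built from
# a reference dimer conformation, virtual-spring protocol, and ensemble
# aggregation of rupture events.
#
# The total energy during pulling is E(x) + (k/2) [L(x) - L0 - v t]^2,
# where E(x) is the conformational (Go) energy, L(x) the instantaneous
# anchor-anchor distance, L0 its initial value, and the spring target
# recedes at v nm per MC sweep.

#' Build a structure-based (Go-type) energy model from a dimer frame
#'
#' Native contacts are CA pairs within `contact_cutoff` in the input
#' conformation (intra-chain pairs with |i - j| <= 2 excluded); each
#' contact gets a 12-10 Lennard-Jones-like well with its minimum at the
#' native distance and depth `epsilon_intra` or `epsilon_inter` (kT).
#' Consecutive CAs are joined by stiff harmonic pseudo-bonds at their
#' observed lengths; all other pairs interact through a purely repulsive
#' r^-12 term.
#'
#' @param frame a two-chain [structure_frame()] with a CA per residue.
#' @param contact_cutoff native-contact cutoff in nm (default 0.8).
#' @param epsilon_intra,epsilon_inter contact well depths in kT.
#' @param bond_stiffness pseudo-bond stiffness (kT/nm^2).
#' @param rep_radius,rep_eps excluded-volume radius (nm) and prefactor (kT).
#' @return object of class `energy_model` holding the CA topology
#'   (`chain`, `residue_index`, native `coords`), `bonds`
#'   (i, j, r0), `contacts` (i, j, sigma, eps, inter), and the repulsion
#'   parameters. Bead indices refer to CA order in the frame.
#' @export
build_energy_model <- function(frame, contact_cutoff = 0.8,
                               epsilon_intra = 1, epsilon_inter = 1,
                               bond_stiffness = 5000,
                               rep_radius = 0.4, rep_eps = 1) {
  stopifnot(inherits(frame, "structure_frame"))
  if (length(chain_ids(frame)) < 2L)
    stop("energy model requires a two-chain (dimer) frame")
  ca <- ca_coords(frame)
  chain <- attr(ca, "chain_id"); resi <- attr(ca, "residue_index")
  n <- nrow(ca)
  bonds <- NULL
  for (i in seq_len(n - 1)) {
    if (chain[i] == chain[i + 1]) {
      bonds <- rbind(bonds, c(i, i + 1, sqrt(sum((ca[i, ] - ca[i + 1, ])^2))))
    }
  }
  d <- as.matrix(dist(ca))
  contacts <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      intra <- chain[i] == chain[j]
      if (intra && abs(i - j) <= 2L) next
      if (d[i, j] > contact_cutoff) next
      eps <- if (intra) epsilon_intra else epsilon_inter
      contacts <- rbind(contacts, c(i, j, d[i, j], eps, as.numeric(!intra)))
    }
  }
  if (is.null(contacts)) contacts <- matrix(numeric(0), 0, 5)
  colnames(contacts) <- c("i", "j", "sigma", "eps", "inter")
  if (!any(contacts[, "inter"] == 1))
    warning("no inter-chain native contacts in the model")
  if (is.null(bonds)) bonds <- matrix(numeric(0), 0, 3)
  colnames(bonds) <- c("i", "j", "r0")
  structure(list(chain = chain, residue_index = resi, coords = ca,
                 bonds = bonds, contacts = contacts,
                 bond_stiffness = bond_stiffness,
                 rep_radius = rep_radius, rep_eps = rep_eps,
                 contact_cutoff = contact_cutoff),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("<energy_model> %d beads, %d bonds, %d contacts (%d inter-chain)\n",
              nrow(x$coords), nrow(x$bonds), nrow(x$contacts),
              sum(x$contacts[, "inter"] == 1)))
  invisible(x)
}

#' Conformational (Go) energy of CA coordinates under a model
#'
#' @param model an [build_energy_model()] result.
#' @param ca n x 3 CA coordinate matrix (nm), bead order as in the model.
#' @return energy in kT.
#' @export
go_energy <- function(model, ca) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  stopifnot(n == nrow(model$coords))
  e <- 0
  bonded <- matrix(FALSE, n, n)
  if (nrow(model$bonds)) {
    for (b in seq_len(nrow(model$bonds))) {
      i <- model$bonds[b, 1]; j <- model$bonds[b, 2]
      r <- sqrt(sum((ca[i, ] - ca[j, ])^2))
      e <- e + 0.5 * model$bond_stiffness * (r - model$bonds[b, 3])^2
      bonded[i, j] <- bonded[j, i] <- TRUE
    }
  }
  if (nrow(model$contacts)) {
    for (c in seq_len(nrow(model$contacts))) {
      i <- model$contacts[c, 1]; j <- model$contacts[c, 2]
      r <- sqrt(sum((ca[i, ] - ca[j, ])^2))
      u <- model$contacts[c, 3] / r
      e <- e + model$contacts[c, 4] * (5 * u^12 - 6 * u^10)
      bonded[i, j] <- bonded[j, i] <- TRUE
    }
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (bonded[i, j]) next
      r <- sqrt(sum((ca[i, ] - ca[j, ])^2))
      e <- e + model$rep_eps * (model$rep_radius / r)^12
    }
  }
  unname(e)
}

#' Pulling protocol parameters
#'
#' @param k virtual-spring constant in pN/nm (default 35, an AFM
#'   cantilever-like stiffness).
#' @param v_fm_per_step anchor-target speed in fm per elementary MC step
#'   (default 0.083, which maps to a 500 nm/s pulling speed; see
#'   [velocity_mapping()]). One sweep advances the target by
#'   `v_fm_per_step * 1e-6 * n_mobile_beads` nm.
#' @param v_nm_per_sweep optional direct override of the per-sweep target
#'   speed in nm (takes precedence when non-NULL).
#' @param L0 initial anchor-anchor distance (nm); NULL = measured from the
#'   input structure.
#' @param temperature temperature in K (converts kT <-> pN nm).
#' @param max_sweeps sweep budget; runs not separated by then are
#'   reported as censored.
#' @param record_stride trace recording stride (sweeps).
#' @param dwell sweeps of sustained zero inter-chain contacts defining
#'   separation.
#' @param move_sigma initial single-bead displacement sigma (nm).
#' @param tune auto-tune `move_sigma` toward ~40% acceptance before
#'   production.
#' @param crank_frac fraction of crankshaft moves (default 0.2, i.e. a
#'   4:1 displacement:crankshaft mix).
#' @param break_factor a native contact counts as formed while
#'   r <= break_factor * sigma.
#' @param pull_residues residues whose CAs are the pull groups, as
#'   `c(chainA_residue, chainB_residue)`; NULL = first residue of each
#'   chain (the N-terminal anchor of each monomer).
#' @param frozen_beads integer bead indices held fixed (testing aid).
#' @param seed RNG seed.
#' @return object of class `pulling_protocol`.
#' @export
pulling_protocol <- function(k = 35, v_fm_per_step = 0.083,
                             v_nm_per_sweep = NULL, L0 = NULL,
                             temperature = 300, max_sweeps = 200000L,
                             record_stride = 50L, dwell = 100L,
                             move_sigma = 0.02, tune = TRUE,
                             crank_frac = 0.2, break_factor = 1.5,
                             pull_residues = NULL, frozen_beads = integer(0),
                             seed = 1L) {
  if (k <= 0) stop("spring constant must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  if (!is.null(v_nm_per_sweep) && v_nm_per_sweep < 0)
    stop("v must be >= 0")
  structure(list(k = k, v_fm_per_step = v_fm_per_step,
                 v_nm_per_sweep = v_nm_per_sweep, L0 = L0,
                 temperature = temperature,
                 max_sweeps = as.integer(max_sweeps),
                 record_stride = as.integer(record_stride),
                 dwell = as.integer(dwell), move_sigma = move_sigma,
                 tune = tune, crank_frac = crank_frac,
                 break_factor = break_factor,
                 pull_residues = pull_residues,
                 frozen_beads = as.integer(frozen_beads),
                 seed = as.integer(seed)),
            class = "pulling_protocol")
}

#' Unit mapping between MC-step speed and laboratory pulling speed
#'
#' The default anchor speed of 0.083 fm per MC step mimics a 500 nm/s
#' AFM pulling speed; the mapping is a pure unit conversion through the
#' implied MC step rate.
#'
#' @param v_fm_per_step speed in fm per MC step.
#' @param speed_nm_s laboratory speed in nm/s.
#' @return list with `steps_per_second` (implied MC step rate),
#'   `v_nm_per_step`, and the echoed inputs.
#' @export
velocity_mapping <- function(v_fm_per_step = 0.083, speed_nm_s = 500) {
  v_nm <- v_fm_per_step * 1e-6
  list(v_fm_per_step = v_fm_per_step, speed_nm_s = speed_nm_s,
       v_nm_per_step = v_nm, steps_per_second = speed_nm_s / v_nm)
}

.resolve_engine_inputs <- function(frame, model, protocol) {
  ca <- model$coords_current
  if (is.null(ca)) {
    ca <- ca_coords(frame)
    if (!identical(attr(ca, "chain_id"), model$chain))
      stop("frame topology does not match the energy model")
  }
  chain <- model$chain
  chains <- unique(chain)
  if (is.null(protocol$pull_residues)) {
    ia <- which(chain == chains[1])[1]
    ib <- which(chain == chains[2])[1]
  } else {
    ia <- which(chain == chains[1] &
                  model$residue_index == protocol$pull_residues[1])[1]
    ib <- which(chain == chains[2] &
                  model$residue_index == protocol$pull_residues[2])[1]
    if (is.na(ia) || is.na(ib)) stop("pull residues not found")
  }
  if (chain[ia] == chain[ib]) stop("pull groups must be on different chains")
  L0 <- protocol$L0
  if (is.null(L0)) L0 <- sqrt(sum((ca[ia, ] - ca[ib, ])^2))
  n_mobile <- nrow(ca) - length(protocol$frozen_beads)
  v_sweep <- if (!is.null(protocol$v_nm_per_sweep)) protocol$v_nm_per_sweep
  else protocol$v_fm_per_step * 1e-6 * n_mobile
  list(ca = ca, ia = ia, ib = ib, L0 = L0, v_sweep = v_sweep)
}

#' Total energy of a conformation under the pulling protocol (Eq.-style)
#'
#' `E(x) + (k/2) [L(x) - L0 - v t]^2` in kT; the spring term vanishes
#' when the anchor-anchor distance equals the receding target.
#'
#' @param model an `energy_model`.
#' @param frame a [structure_frame()] matching the model topology.
#' @param protocol a [pulling_protocol()].
#' @param t MC time in sweeps.
#' @return total energy in kT.
#' @export
total_energy <- function(model, frame, protocol, t = 0) {
  inp <- .resolve_engine_inputs(frame, model, protocol)
  kT <- kT_pN_nm(protocol$temperature)
  L <- sqrt(sum((inp$ca[inp$ia, ] - inp$ca[inp$ib, ])^2))
  spring <- 0.5 * (protocol$k / kT) * (L - inp$L0 - inp$v_sweep * t)^2
  go_energy(model, inp$ca) + spring
}

#' Run one Monte Carlo pulling simulation
#'
#' Metropolis MC on CA beads under the Go energy plus the virtual-spring
#' term; the spring target recedes at v nm/sweep along the (free)
#' anchor-anchor distance. The trace records the spring extension
#' `force = k (L - L0 - v t)` (negative while the chain resists the
#' receding target); the rupture force is the maximal force magnitude
#' before inter-chain native contacts vanish for `dwell` consecutive
#' sweeps.
#'
#' @param frame reference [structure_frame()] (start conformation).
#' @param model an [build_energy_model()] result for `frame`.
#' @param protocol a [pulling_protocol()].
#' @return object of class `pulling_trace`: data.frame `trace`
#'   (sweep, L, force_pN signed, n_inter_contacts), `ruptured` flag
#'   (FALSE = censored), `rupture_force` (pN, magnitude),
#'   `rupture_position` (nm, L at rupture minus L0), `rupture_sweep`,
#'   `acceptance`, `move_sigma`, `L0`, `v_nm_per_sweep`, `protocol`.
#' @export
run_pulling <- function(frame, model, protocol = pulling_protocol()) {
  stopifnot(inherits(model, "energy_model"),
            inherits(protocol, "pulling_protocol"))
  inp <- .resolve_engine_inputs(frame, model, protocol)
  kT <- kT_pN_nm(protocol$temperature)
  frozen <- rep(FALSE, nrow(inp$ca))
  frozen[protocol$frozen_beads] <- TRUE
  set.seed(protocol$seed)
  res <- mcp_run_cpp(inp$ca, as.integer(factor(model$chain)),
                     matrix(as.integer(model$bonds[, 1:2]), ncol = 2),
                     model$bonds[, 3], model$bond_stiffness,
                     matrix(as.integer(model$contacts[, 1:2]), ncol = 2),
                     model$contacts[, 3], model$contacts[, 4],
                     model$contacts[, 5] == 1,
                     model$rep_radius, model$rep_eps,
                     inp$ia, inp$ib, frozen,
                     protocol$k / kT, inp$L0, inp$v_sweep,
                     protocol$max_sweeps, protocol$record_stride,
                     protocol$dwell, protocol$move_sigma, protocol$tune,
                     protocol$crank_frac, 1.0, protocol$break_factor)
  tr <- as.data.frame(res$trace)
  names(tr) <- c("sweep", "L", "force_pN", "n_inter_contacts")
  tr$force_pN <- tr$force_pN * kT
  structure(list(trace = tr, ruptured = res$ruptured,
                 rupture_force = res$rupture_force_kT_nm * kT,
                 rupture_position = res$rupture_L - inp$L0,
                 rupture_sweep = res$rupture_sweep,
                 sweeps_done = res$sweeps_done,
                 acceptance = res$acceptance,
                 move_sigma = res$sigma_final,
                 L0 = inp$L0, v_nm_per_sweep = inp$v_sweep,
                 final_coords = res$coords, protocol = protocol),
            class = "pulling_trace")
}

#' @export
print.pulling_trace <- function(x, ...) {
  cat(sprintf("<pulling_trace> %d sweeps, %s; rupture force %.1f pN at L - L0 = %.2f nm\n",
              x$sweeps_done,
              if (x$ruptured) "ruptured" else "censored",
              x$rupture_force, x$rupture_position))
  invisible(x)
}

#' Aggregate rupture statistics over conformations and seeds
#'
#' Runs `n_runs_per_conf` pulling simulations (distinct seeds) for every
#' frame of `conformations` and collects the rupture forces and
#' positions. Censored runs are excluded from the dataset but counted in
#' the metadata.
#'
#' @param conformations an [ensemble()] of dimer frames.
#' @param protocol a [pulling_protocol()]; per-run seeds are derived from
#'   `protocol$seed`.
#' @param n_runs_per_conf pulls per conformation.
#' @param contour_length optional contour length (nm) to normalize
#'   rupture positions.
#' @param label dataset label.
#' @param ... passed to [build_energy_model()].
#' @return a [rupture_dataset()] with attribute `runs` (per-run
#'   data.frame: conformation, seed, ruptured, force, position).
#' @export
pull_ensemble <- function(conformations, protocol = pulling_protocol(),
                          n_runs_per_conf = 1L, contour_length = NULL,
                          label = "mcp", ...) {
  stopifnot(inherits(conformations, "ensemble"))
  rows <- list()
  counter <- 0L
  for (ci in seq_len(n_frames(conformations))) {
    fr <- conformations$frames[[ci]]
    model <- build_energy_model(fr, ...)
    for (run in seq_len(n_runs_per_conf)) {
      counter <- counter + 1L
      p <- protocol
      p$seed <- (protocol$seed + 7919L * counter) %% 2147483647L
      res <- run_pulling(fr, model, p)
      rows[[counter]] <- data.frame(conformation = ci, seed = p$seed,
                                    ruptured = res$ruptured,
                                    force = res$rupture_force,
                                    position = res$rupture_position)
    }
  }
  runs <- do.call(rbind, rows)
  ok <- runs$ruptured & runs$force >= 0 & runs$position >= 0
  if (!any(ok)) stop("all pulling runs were censored")
  pos <- runs$position[ok]
  normalized <- FALSE
  if (!is.null(contour_length)) {
    pos <- pos / contour_length
    keep <- pos >= 0 & pos <= 1
    ds <- rupture_dataset(runs$force[ok][keep], pos[keep], label, TRUE)
  } else {
    ds <- rupture_dataset(runs$force[ok], pos, label, normalized)
  }
  attr(ds, "runs") <- runs
  ds
}
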