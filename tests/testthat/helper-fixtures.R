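# Shared fixtures and independent oracles. Everything is generated in
# code; the beta-sheet placement parameters were frozen after validating
# the resulting labels against an independent reference DSSP
# implementation run on the identical structure.

make_helix_frame <- function(n = 12L, chain_id = "A") {
  build_backbone(rep(-57, n), rep(-47, n), chain_id = chain_id)
}

# reference DSSP labels for make_helix_frame(12): "-HHHHHHHHHH-"
helix12_oracle_labels <- c("C", rep("H", 10), "C")

.rotmat_axis <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# two antiparallel 8-residue strands; rigid placement of the second chain
# optimized once against the Kabsch-Sander inter-chain H-bond energy
make_beta_sheet_frame <- function() {
  a <- build_backbone(rep(-140, 8), rep(135, 8), chain_id = "A")
  par <- c(-0.08913970, -0.11567528, 1.10891758,
           0.16388287, 0.37115866, 0.21555259)
  R <- .rotmat_axis(par[1:3]) %*% diag(c(1, -1, -1))
  bco <- sweep(a$coords %*% t(R), 2, par[4:6], "+")
  structure_frame(rbind(a$coords, bco), rep(a$atom_name, 2),
                  rep(a$residue_index, 2), rep(a$residue_name, 2),
                  rep(c("A", "B"), each = nrow(a$coords)))
}

# reference DSSP on the same structure: "---EEEEE--EEEEE-"
sheet_oracle_labels <- strsplit("CCCEEEEECCEEEEEC", "")[[1]]

# two single-residue chains with CA beads at distance d along x
make_two_bead_dimer <- function(d = 0.5) {
  structure_frame(rbind(c(0, 0, 0), c(d, 0, 0)), c("CA", "CA"), c(1L, 1L),
                  "CYS", c("A", "B"))
}

# two parallel n-bead CA strands separated by `sep` nm (a contact ladder)
make_ladder_dimer <- function(n = 10L, sep = 0.55, bond = 0.38) {
  co <- rbind(cbind((seq_len(n) - 1) * bond, 0, 0),
              cbind((seq_len(n) - 1) * bond, sep, 0))
  structure_frame(co, "CA", c(seq_len(n), seq_len(n)), "ALA",
                  rep(c("A", "B"), each = n))
}

# ---- independent oracles ----------------------------------------------

# brute-force GROMOS clustering, written directly from the procedure
# description with explicit loops (independent of the package code path)
bf_gromos <- function(rmsd, cutoff) {
  Tn <- nrow(rmsd)
  remaining <- seq_len(Tn)
  centers <- integer(0)
  members <- list()
  while (length(remaining)) {
    counts <- integer(length(remaining))
    for (a in seq_along(remaining)) {
      for (b in seq_along(remaining)) {
        if (rmsd[remaining[a], remaining[b]] <= cutoff)
          counts[a] <- counts[a] + 1L
      }
    }
    best <- remaining[which(counts == max(counts))]
    center <- min(best)                       # tie-break: lowest index
    cl <- remaining[rmsd[remaining, center] <= cutoff]
    cl <- sort(unique(c(cl, center)))
    centers <- c(centers, center)
    members[[length(members) + 1L]] <- cl
    remaining <- setdiff(remaining, cl)
  }
  pop <- sapply(members, length) / Tn
  ord <- order(-pop, centers)
  assignments <- integer(Tn)
  for (k in seq_along(ord)) assignments[members[[ord[k]]]] <- k
  list(assignments = assignments, representatives = centers[ord],
       populations = pop[ord])
}

# brute-force two-sample KS statistic: maximum ECDF gap by enumeration
bf_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  gaps <- vapply(pts, function(x) {
    abs(mean(a <= x) - mean(b <= x))
  }, numeric(1))
  max(gaps)
}

# dihedral-box predicate, written independently of the package
bf_in_alpha <- function(phi, psi) {
  !is.na(phi) & !is.na(psi) & phi >= -80 & phi <= -48 & psi >= -59 & psi <= -27
}
bf_in_beta <- function(phi, psi) {
  !is.na(phi) & !is.na(psi) & phi >= -150 & phi <= -90 & psi >= 90 & psi <= 150
}

# brute-force consecutive-pair label scan over a dihedral series
bf_pair_labels <- function(phi, psi) {
  Tn <- nrow(phi); R <- ncol(phi)
  lab <- matrix("coil", Tn, R)
  for (t in seq_len(Tn)) {
    for (i in seq_len(R - 1)) {
      if (bf_in_alpha(phi[t, i], psi[t, i]) &&
          bf_in_alpha(phi[t, i + 1], psi[t, i + 1]))
        lab[t, c(i, i + 1)] <- "alpha"
      if (bf_in_beta(phi[t, i], psi[t, i]) &&
          bf_in_beta(phi[t, i + 1], psi[t, i + 1]))
        lab[t, c(i, i + 1)] <- "beta"
    }
  }
  lab
}

# enumeration oracle: probability that residue i is labeled alpha under
# the pair rule, for i.i.d. per-residue states with P(alpha) = p.
# Residues 1 and n can never satisfy a pair (undefined phi / psi).
bf_alpha_label_prob <- function(p, n) {
  states <- c("alpha", "other")
  probs <- c(p, 1 - p)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1L || i == n) { out[i] <- 0; next }
    left_ok <- i - 1 >= 2            # pair (i-1, i) usable
    right_ok <- i + 1 <= n - 1       # pair (i, i+1) usable
    pr <- 0
    for (si in states) for (sl in states) for (sr in states) {
      p_comb <- probs[match(si, states)] * probs[match(sl, states)] *
        probs[match(sr, states)]
      hit <- (left_ok && si == "alpha" && sl == "alpha") ||
        (right_ok && si == "alpha" && sr == "alpha")
      if (hit) pr <- pr + p_comb
    }
    out[i] <- pr
  }
  out
}

# brute-force convex hull volume: sum of facet tetrahedra where facets are
# all point triples with every other point strictly on one side (O(n^4))
bf_hull_volume <- function(pts) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  vol <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    nrm <- crossprod_vec(pts[j, ] - pts[i, ], pts[k, ] - pts[i, ])
    if (sqrt(sum(nrm^2)) < 1e-12) next
    s <- (pts %*% nrm) - sum(nrm * pts[i, ])
    eps <- 1e-9 * max(abs(s))
    if (all(s <= eps) || all(s >= -eps)) {
      a <- pts[i, ] - ctr; b <- pts[j, ] - ctr; c <- pts[k, ] - ctr
      vol <- vol + abs(sum(a * crossprod_vec(b, c))) / 6
    }
  }
  vol
}
crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# numeric oracle: maximal slope of the 12-10 contact well (force to
# escape), in kT/nm, for depth eps (kT) and native distance sigma (nm)
bf_max_contact_force <- function(eps, sigma) {
  dU <- function(r) eps * (60 * sigma^10 / r^11 - 60 * sigma^12 / r^13)
  opt <- optimize(function(r) -dU(r), c(sigma, 3 * sigma))
  -opt$objective
}
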