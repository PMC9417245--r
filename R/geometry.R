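# Vector geometry: dihedrals, internal-coordinate atom placement (NeRF),
# backbone construction from (phi, psi), and Kabsch superposition.

.vnorm <- function(v) sqrt(sum(v * v))
.unit <- function(v) v / .vnorm(v)
.cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Dihedral angle of four points
#'
#' IUPAC sign convention: looking from `p2` to `p3`, the angle from the
#' plane (p1,p2,p3) to (p2,p3,p4); cis = 0, trans = 180.
#'
#' @param p1,p2,p3,p4 numeric length-3 vectors or n x 3 matrices.
#' @return angle(s) in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  if (is.null(dim(p1))) {
    p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3); p4 <- rbind(p4)
  }
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  c12 <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
               b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
               b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
  c23 <- cbind(b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
               b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
               b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
  b2n <- sqrt(rowSums(b2 * b2))
  x <- rowSums(c12 * c23)
  y <- rowSums(b1 * c23) * b2n
  ang <- atan2(y, x) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  if (length(ang) == 1L) ang[[1]] else ang
}

#' Place an atom from internal coordinates (NeRF)
#'
#' @param a,b,c positions of the three reference atoms (the new atom bonds
#'   to `c`; `b`-`c` defines the bond angle; `a` the torsion).
#' @param bond bond length (nm), angle bond angle (degrees),
#'   torsion dihedral a-b-c-new (degrees).
#' @param angle,torsion see above.
#' @return length-3 position.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Ideal backbone geometry (nm / degrees)
.geom <- list(b_n_ca = 0.1458, b_ca_c = 0.1525, b_c_n = 0.1329,
              b_c_o = 0.1231, b_ca_cb = 0.1530,
              a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
              a_ca_c_o = 120.8, omega = 180)

#' Build a peptide backbone from dihedral angles
#'
#' Rebuilds N, CA, C, O (and CB except for glycine) at ideal bond geometry
#' with omega = 180. `phi[1]` and `psi[n]` are not used for backbone
#' placement (undefined at the termini).
#'
#' @param phi,psi numeric vectors of length n (degrees); `phi[1]`/`psi[n]`
#'   may be NA.
#' @param residue_name three-letter codes, recycled to length n.
#' @param chain_id chain identifier.
#' @param with_cb place CB stubs (tetrahedral, ideal) on non-Gly residues.
#' @return a [structure_frame()].
#' @export
build_backbone <- function(phi, psi, residue_name = "ALA", chain_id = "A",
                           with_cb = TRUE) {
  n <- length(phi)
  if (length(psi) != n) stop("phi and psi must have equal length")
  if (n < 2L) stop("need at least 2 residues")
  residue_name <- rep_len(residue_name, n)
  g <- .geom
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  # seed residue in the xy-plane
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$b_c_n, g$a_ca_c_n, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$b_n_ca, g$a_c_n_ca, g$omega)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           g$b_ca_c, g$a_n_ca_c, phi[i])
    }
    psi_i <- if (i < n) psi[i] else if (is.finite(psi[i])) psi[i] else 180
    # carbonyl O: trans to the next backbone N across the C-N peptide bond
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o,
                         psi_i + 180)
  }
  atoms <- c("N", "CA", "C", "O")
  per_res <- lapply(seq_len(n), function(i) {
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    nm <- atoms
    if (with_cb && residue_name[i] != "GLY") {
      cb <- place_atom(C[i, ], N[i, ], CA[i, ], g$b_ca_cb, 110.6, 123.2)
      xyz <- rbind(xyz, cb); nm <- c(nm, "CB")
    }
    list(xyz = xyz, nm = nm)
  })
  coords <- do.call(rbind, lapply(per_res, `[[`, "xyz"))
  nm <- unlist(lapply(per_res, `[[`, "nm"))
  cnt <- vapply(per_res, function(p) length(p$nm), integer(1))
  structure_frame(coords, nm, rep(seq_len(n), cnt),
                  rep(residue_name, cnt), rep(chain_id, sum(cnt)))
}

#' Optimal least-squares superposition (Kabsch)
#'
#' Rotates and translates `mobile` onto `reference` minimizing the RMSD of
#' the selected atoms; the whole mobile frame is transformed.
#'
#' @param mobile,reference `structure_frame`s.
#' @param atoms atom-name selection used for the fit (default backbone
#'   N/CA/C); both frames must select the same atom count.
#' @return list with `frame` (transformed mobile) and `rmsd` (nm, over the
#'   selection).
#' @export
superpose <- function(mobile, reference, atoms = c("N", "CA", "C")) {
  mm <- atom_mask(mobile, atoms = atoms)
  mr <- atom_mask(reference, atoms = atoms)
  P <- mobile$coords[mm, , drop = FALSE]
  Q <- reference$coords[mr, , drop = FALSE]
  if (nrow(P) != nrow(Q)) stop("selection sizes differ between frames")
  if (nrow(P) < 3L) stop("need at least 3 atoms to superpose")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- crossprod(P0, Q0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  newco <- sweep(sweep(mobile$coords, 2, cp) %*% t(R), 2, cq, "+")
  out <- mobile; out$coords <- newco
  fitted <- sweep(P0 %*% t(R), 2, cq, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(frame = out, rmsd = rmsd)
}

.rand_rotation <- function() {
  # uniform random rotation via quaternion
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]), sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]), sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
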