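#' Construct a single-conformation structure frame
#'
#' The basic container of the package: one conformation of one or more
#' peptide chains, stored as per-atom coordinates (in nm) plus atom-level
#' topology labels. All analysis stages consume this type or an
#' [ensemble()] of it.
#'
#' @param coords numeric n x 3 matrix of positions in nm.
#' @param atom_name character atom labels ("N", "CA", "C", "O", ...).
#' @param residue_index integer residue number per atom, 1-based,
#'   non-decreasing within a chain.
#' @param residue_name three-letter residue code per atom.
#' @param chain_id single-character chain identifier per atom.
#' @return object of class `structure_frame`.
#' @export
structure_frame <- function(coords, atom_name, residue_index, residue_name,
                            chain_id) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  n <- nrow(coords)
  if (n == 0L) stop("structure_frame needs at least one atom")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  recycle1 <- function(v) if (length(v) == 1L) rep(v, n) else v
  atom_name <- recycle1(as.character(atom_name))
  residue_index <- recycle1(as.integer(residue_index))
  residue_name <- recycle1(as.character(residue_name))
  chain_id <- recycle1(as.character(chain_id))
  lens <- c(length(atom_name), length(residue_index), length(residue_name),
            length(chain_id))
  if (any(lens != n)) stop("atom annotation lengths must match nrow(coords)")
  for (ch in unique(chain_id)) {
    ri <- residue_index[chain_id == ch]
    if (is.unsorted(ri)) stop("residue indices must be non-decreasing within a chain")
  }
  dimnames(coords) <- NULL
  structure(list(coords = coords, atom_name = atom_name,
                 residue_index = residue_index, residue_name = residue_name,
                 chain_id = chain_id),
            class = "structure_frame")
}

#' @export
print.structure_frame <- function(x, ...) {
  cat(sprintf("<structure_frame> %d atoms, %d chain(s): %s\n",
              nrow(x$coords), length(unique(x$chain_id)),
              paste(sprintf("%s (%d res)", chain_ids(x),
                            vapply(chain_ids(x), function(ch)
                              length(unique(x$residue_index[x$chain_id == ch])),
                              integer(1))),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname structure_frame
#' @param x a `structure_frame`.
#' @export
n_atoms <- function(x) nrow(x$coords)

#' Chain identifiers present in a frame
#' @param frame a `structure_frame`.
#' @return character vector of chain ids, in order of first appearance.
#' @export
chain_ids <- function(frame) unique(frame$chain_id)

#' Subset a frame by atom mask
#' @param frame a `structure_frame`.
#' @param mask logical or integer atom selector.
#' @return a new `structure_frame`.
#' @export
subset_atoms <- function(frame, mask) {
  structure_frame(frame$coords[mask, , drop = FALSE], frame$atom_name[mask],
                  frame$residue_index[mask], frame$residue_name[mask],
                  frame$chain_id[mask])
}

#' Select atoms by name and/or chain
#'
#' @param frame a `structure_frame`.
#' @param atoms atom names to keep (NULL keeps all).
#' @param chain chain id(s) to keep (NULL keeps all).
#' @return logical atom mask.
#' @export
atom_mask <- function(frame, atoms = NULL, chain = NULL) {
  m <- rep(TRUE, n_atoms(frame))
  if (!is.null(atoms)) m <- m & frame$atom_name %in% atoms
  if (!is.null(chain)) m <- m & frame$chain_id %in% chain
  m
}

#' C-alpha coordinates of a frame
#'
#' @param frame a `structure_frame`.
#' @param chain optional chain id filter.
#' @return matrix of CA positions (nm), one row per residue, with the
#'   residue index and chain id attached as attributes.
#' @export
ca_coords <- function(frame, chain = NULL) {
  m <- atom_mask(frame, atoms = "CA", chain = chain)
  if (!any(m)) stop("no CA atoms in selection")
  out <- frame$coords[m, , drop = FALSE]
  attr(out, "residue_index") <- frame$residue_index[m]
  attr(out, "chain_id") <- frame$chain_id[m]
  out
}

#' Topology fingerprint of a frame
#'
#' Identifier asserting two frames share atom count, ordering, atom names,
#' residue numbering and chain layout (coordinates excluded).
#' @param frame a `structure_frame`.
#' @return character scalar.
#' @export
topology_id <- function(frame) {
  key <- paste(frame$atom_name, frame$residue_index, frame$residue_name,
               frame$chain_id, sep = "|", collapse = ";")
  # cheap stable hash: length + polynomial roll over UTF-8 bytes
  b <- utf8ToInt(key)
  h <- 0
  for (chunk in split(b, ceiling(seq_along(b) / 512))) {
    h <- (h * 31 + sum(chunk * seq_along(chunk))) %% 2147483647
  }
  sprintf("%d-%d", length(b), as.integer(h))
}

#' Construct an ordered ensemble of structure frames
#'
#' @param frames list of [structure_frame()] objects sharing one topology.
#' @param times optional strictly increasing frame times (ns).
#' @return object of class `ensemble`.
#' @export
ensemble <- function(frames, times = NULL) {
  if (!length(frames)) stop("ensemble needs at least one frame")
  ids <- vapply(frames, topology_id, character(1))
  if (length(unique(ids)) != 1L)
    stop("all frames must share one topology (atom count/order)")
  if (!is.null(times)) {
    times <- as.numeric(times)
    if (length(times) != length(frames))
      stop("times length must equal frame count")
    if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  }
  structure(list(frames = frames, times = times, topology_hash = ids[[1]]),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d frames of %d atoms%s\n", length(x$frames),
              n_atoms(x$frames[[1]]),
              if (is.null(x$times)) "" else
                sprintf(", t = %.4g..%.4g ns", min(x$times), max(x$times))))
  invisible(x)
}

#' @rdname ensemble
#' @param x an `ensemble`.
#' @export
n_frames <- function(x) length(x$frames)

#' Concatenate ensembles sharing one topology
#' @param ... ensembles.
#' @return a single `ensemble` (times dropped unless all parts carry
#'   compatible, strictly increasing times when concatenated).
#' @export
concat_ensembles <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "ensemble")) parts <- parts[[1]]
  hashes <- vapply(parts, function(e) e$topology_hash, character(1))
  if (length(unique(hashes)) != 1L) stop("topology mismatch across ensembles")
  frames <- do.call(c, lapply(parts, function(e) e$frames))
  times <- NULL
  if (all(!vapply(parts, function(e) is.null(e$times), logical(1)))) {
    tt <- do.call(c, lapply(parts, function(e) e$times))
    if (!any(diff(tt) <= 0)) times <- tt
  }
  ensemble(frames, times)
}

#' Construct a rupture dataset
#'
#' Carrier for force-spectroscopy rupture events: rupture force plus the
#' rupture position along the pulling coordinate, either in nm or
#' normalized by contour length to `[0, 1]`.
#'
#' @param forces numeric rupture forces (pN), non-negative.
#' @param positions numeric rupture positions (nm, or dimensionless when
#'   `normalized`).
#' @param label free-text dataset label.
#' @param normalized logical; TRUE when positions are contour-length
#'   normalized.
#' @return object of class `rupture_dataset`.
#' @export
rupture_dataset <- function(forces, positions, label = "", normalized = FALSE) {
  forces <- as.numeric(forces); positions <- as.numeric(positions)
  if (length(forces) != length(positions))
    stop("forces and positions must have the same length")
  if (any(!is.finite(forces)) || any(!is.finite(positions)))
    stop("non-finite rupture values")
  if (any(forces < 0)) stop("rupture forces must be >= 0")
  if (normalized && length(positions) &&
      (min(positions) < 0 || max(positions) > 1))
    stop("normalized positions must lie in [0, 1]")
  structure(list(forces = forces, positions = positions,
                 label = as.character(label)[1],
                 normalized = isTRUE(normalized)),
            class = "rupture_dataset")
}

#' @export
print.rupture_dataset <- function(x, ...) {
  cat(sprintf("<rupture_dataset> '%s': %d events, force %.3g +/- %.3g pN, %s positions\n",
              x$label, length(x$forces),
              if (length(x$forces)) mean(x$forces) else NA,
              if (length(x$forces) > 1) sd(x$forces) else NA,
              if (x$normalized) "normalized" else "nm"))
  invisible(x)
}

#' @export
length.rupture_dataset <- function(x) length(x$forces)
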