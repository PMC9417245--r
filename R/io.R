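# Structure and table IO. PDB is the interchange format: coordinates are
# Angstrom on disk (PDB convention) and nm in memory.

.guess_element <- function(atom_name) {
  nm <- gsub("[0-9']", "", trimws(atom_name))
  ifelse(substr(nm, 1, 1) %in% c("N", "C", "O", "S", "H"),
         substr(nm, 1, 1), "C")
}

#' Read a (multi-model) PDB file into an ensemble
#'
#' ATOM/HETATM records are parsed by fixed PDB v3 columns; MODEL/ENDMDL
#' blocks become ensemble frames. Coordinates are converted to nm.
#'
#' @param path PDB file path.
#' @param model_policy `"all"` (every model becomes a frame) or `"first"`.
#' @return an [ensemble()].
#' @export
read_structure <- function(path, model_policy = c("all", "first")) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  model_no <- cumsum(trimws(rec) == "MODEL")
  if (max(model_no) == 0L) model_no <- rep(1L, length(lines))
  model_no[model_no == 0L] <- 1L
  keep <- which(is_atom)
  if (!length(keep)) stop("no ATOM records in ", path)
  models <- split(keep, model_no[keep])
  if (model_policy == "first") models <- models[1]
  parse_block <- function(idx) {
    ln <- lines[idx]
    coords <- cbind(as.numeric(substr(ln, 31, 38)),
                    as.numeric(substr(ln, 39, 46)),
                    as.numeric(substr(ln, 47, 54))) / 10  # Angstrom -> nm
    if (any(!is.finite(coords))) stop("unparseable coordinates in ", path)
    structure_frame(coords,
                    atom_name = trimws(substr(ln, 13, 16)),
                    residue_index = as.integer(substr(ln, 23, 26)),
                    residue_name = trimws(substr(ln, 18, 20)),
                    chain_id = substr(ln, 22, 22))
  }
  frames <- lapply(models, parse_block)
  counts <- vapply(frames, n_atoms, integer(1))
  if (length(unique(counts)) != 1L)
    stop("inconsistent atom counts across models in ", path)
  e <- ensemble(unname(frames))
  if (!any(atom_mask(e$frames[[1]], atoms = "CA")))
    stop("structure has no CA atoms: ", path)
  e
}

#' Write a frame or ensemble as a (multi-model) PDB file
#'
#' @param x a [structure_frame()] or [ensemble()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "structure_frame")) x <- ensemble(list(x))
  if (!inherits(x, "ensemble")) stop("x must be a structure_frame or ensemble")
  multi <- n_frames(x) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(x))) {
    f <- x$frames[[i]]
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    xyz <- f$coords * 10  # nm -> Angstrom
    nm <- f$atom_name
    nm4 <- ifelse(nchar(nm) < 4, sprintf(" %-3s", nm), substr(nm, 1, 4))
    writeLines(sprintf(
      "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(xyz)) %% 100000L, nm4, f$residue_name,
      substr(f$chain_id, 1, 1), f$residue_index %% 10000L,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, .guess_element(nm)), con)
    writeLines(if (multi) "ENDMDL" else "TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a tabular rupture dataset (CSV/TSV)
#'
#' Expects columns named `force` and `position` (case-insensitive; a
#' `normalized` column or an explicit argument sets the position scale).
#' Headerless two-column files are read as (force, position).
#'
#' @param path delimited text file.
#' @param normalized optional logical override for the position scale.
#' @param label dataset label (defaults to file name).
#' @return a [rupture_dataset()].
#' @export
read_rupture_table <- function(path, normalized = NULL, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first) || !nzchar(trimws(first))) stop("empty rupture table: ", path)
  sep <- if (grepl(",", first)) "," else ""
  has_header <- grepl("[A-Za-z]", first)
  df <- read.table(path, header = has_header, sep = sep,
                   stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty rupture table: ", path)
  names(df) <- tolower(names(df))
  if (has_header) {
    fcol <- grep("force", names(df))[1]
    pcol <- grep("pos|dist", names(df))[1]
    if (is.na(fcol) || is.na(pcol))
      stop("need force and position columns in ", path)
  } else {
    fcol <- 1L; pcol <- 2L
  }
  if (!is.numeric(df[[fcol]]) || !is.numeric(df[[pcol]]))
    stop("non-numeric rows in rupture table ", path)
  if (is.null(normalized)) {
    normalized <- if ("normalized" %in% names(df)) {
      isTRUE(all(as.logical(df$normalized)))
    } else FALSE
  }
  rupture_dataset(df[[fcol]], df[[pcol]], label = label,
                  normalized = normalized)
}

#' Write a rupture dataset as TSV
#'
#' @param dataset a [rupture_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rupture_table <- function(dataset, path) {
  df <- data.frame(force = dataset$forces, position = dataset$positions,
                   normalized = dataset$normalized)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
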