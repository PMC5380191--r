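# PDB reading (via bio3d) and multi-model writing.

#' Read a (possibly multi-model) PDB file as a trajectory
#'
#' Single-model files yield one frame; MODEL/ENDMDL blocks yield one frame
#' each, in file order. Atom ordering is preserved. Parsing is delegated to
#' \pkg{bio3d}; a consistency pre-scan rejects files whose models differ in
#' atom count, naming the offending model.
#'
#' @param path Path to a PDB file.
#' @return A [peptrajectory()].
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  model_starts <- grepl("^MODEL", lines)
  if (any(model_starts)) {
    model_id <- cumsum(model_starts)
    counts <- table(model_id[is_atom])
    if (length(unique(as.integer(counts))) != 1L) {
      bad <- names(counts)[which(as.integer(counts) != as.integer(counts[1L]))[1L]]
      stop(sprintf("model %s has a different atom count than model 1", bad))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  elements <- atom$elesy
  if (is.null(elements) || all(!nzchar(trimws(elements))))
    elements <- substr(trimws(atom$elety), 1L, 1L)
  elements <- trimws(elements)
  elements[!nzchar(elements)] <- substr(trimws(atom$elety)[!nzchar(elements)], 1L, 1L)
  nmod <- nrow(pdb$xyz)
  frames <- lapply(seq_len(nmod), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
    pepstructure(trimws(atom$elety), trimws(atom$resid),
                 atom$resno, elements, xyz)
  })
  peptrajectory(frames)
}

#' Write a structure or trajectory as a PDB file
#'
#' Writes fixed-width ATOM records (coordinates at the format's 1e-3
#' Angstrom precision). Multi-frame trajectories are written as
#' MODEL/ENDMDL blocks.
#'
#' @param x A [pepstructure()] or [peptrajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "pepstructure")) x <- peptrajectory(list(x))
  if (!inherits(x, "peptrajectory")) stop("x must be a pepstructure or peptrajectory")
  s1 <- x$frames[[1L]]
  fmt_atom <- function(i, xyz) {
    nm <- s1$atom_names[i]
    # PDB atom-name column convention: 1-char element names start in col 14
    nm_f <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else nm
    sprintf("ATOM  %5d %4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, nm_f, s1$residue_names[i], s1$residue_indices[i],
            xyz[i, 1L], xyz[i, 2L], xyz[i, 3L], s1$elements[i])
  }
  out <- character(0)
  multi <- length(x$frames) > 1L
  for (m in seq_along(x$frames)) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", m))
    xyz <- x$frames[[m]]$coordinates
    out <- c(out, vapply(seq_len(n_atoms(s1)), fmt_atom, character(1), xyz = xyz))
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}
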