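# PDB input/output. Parsing and writing go through bio3d; this file only
# converts between bio3d's atom records and the package's tidy atom table.

bio3d_to_structure <- function(pdb) {
  at <- pdb$atom
  keep <- at$type == "ATOM"
  at <- at[keep, , drop = FALSE]
  stop_if_not(nrow(at) > 0, "no ATOM records found")
  # altloc resolution: highest occupancy first, then altloc A; original
  # atom order is preserved otherwise
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$.ord <- seq_len(nrow(at))
  key <- paste(at$chain, at$resno, at$elety)
  pick <- unlist(lapply(split(seq_len(nrow(at)), factor(key, unique(key))),
                        function(i) {
    i[order(-at$o[i], at$alt[i])][1]
  }), use.names = FALSE)
  at <- at[sort(pick), , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | elem == "")) {
    elem <- substr(trimws(at$elety), 1, 1)
  }
  new_structure(tibble(
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    resno = as.integer(at$resno),
    resname = at$resid,
    atom = trimws(at$elety),
    element = toupper(trimws(elem)),
    x = at$x, y = at$y, z = at$z
  ))
}

#' Read a protein structure from a PDB file
#'
#' Single-model read; alternate locations are resolved deterministically
#' (highest occupancy, then altloc A). Coordinates are in Angstrom.
#'
#' @param source Path to a PDB file.
#' @return A `structure_tbl` tibble.
#' @export
read_structure <- function(source) {
  pdb <- bio3d::read.pdb(source, verbose = FALSE)
  bio3d_to_structure(pdb)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL becomes one frame; all models must have the same atom count.
#'
#' @param source Path to a multi-model PDB file.
#' @param dt_ns Time between frames in ns (frame times are `0, dt_ns, ...`;
#'   PDB files carry no time stamps).
#' @return A `trajectory`.
#' @export
read_trajectory <- function(source, dt_ns = 1) {
  pdb <- bio3d::read.pdb(source, multi = TRUE, verbose = FALSE)
  topo <- bio3d_to_structure(pdb)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  stop_if_not(ncol(xyz) == 3 * nrow(topo),
              "atom count mismatch across models (topology %d atoms, frames carry %g)",
              nrow(topo), ncol(xyz) / 3)
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  new_trajectory(topo, frames, times = (seq_len(nrow(xyz)) - 1) * dt_ns)
}

#' Write a structure or trajectory to a PDB file
#'
#' @param x A `structure_tbl` or `trajectory` (written as a multi-model
#'   file).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_structure <- function(x, file) {
  if (inherits(x, "trajectory")) {
    topo <- x$topology
    xyz <- do.call(rbind, lapply(x$frames, function(f) as.vector(t(f))))
  } else {
    topo <- x
    xyz <- as.vector(t(structure_coords(x)))
  }
  bio3d::write.pdb(
    file = file,
    xyz = xyz,
    resno = topo$resno,
    resid = topo$resname,
    chain = topo$chain,
    elety = topo$atom,
    eleno = seq_len(nrow(topo)),
    elesy = topo$element
  )
  invisible(file)
}
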