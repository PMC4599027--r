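# PDB structure / multi-model trajectory I/O ---------------------------------

#' Read a protein structure from PDB text
#'
#' Thin wrapper around [bio3d::read.pdb()] exposing a plain atom table.
#' When the element column is blank the element is inferred from the atom
#' name.
#'
#' @param source File path, single PDB string, or character vector of lines.
#' @return An object of class `structure`: a list with `atoms` (data frame
#'   with `serial`, `atom`, `resname`, `resno`, `chain`, `element`) and
#'   `coords` (n x 3 matrix, Angstrom).
#' @export
read_structure <- function(source) {
  lines <- .source_lines(source)
  .structure_from_lines(lines, model = 1L)
}

#' Read a trajectory from multi-model PDB text
#'
#' `MODEL`/`ENDMDL` records delimit frames; all frames must share the
#' topology (atom count) of the first. A file without `MODEL` records is
#' read as a single-frame trajectory.
#'
#' @inheritParams read_structure
#' @return An object of class `trajectory`: `topology` (a `structure`),
#'   `frames` (list of n x 3 coordinate matrices) and `n_frames`.
#' @export
read_trajectory <- function(source) {
  lines <- .source_lines(source)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) {
    topo <- .structure_from_lines(lines, model = 1L)
    return(structure(list(topology = topo, frames = list(topo$coords),
                          n_frames = 1L), class = "trajectory"))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts))
    stop("unbalanced MODEL/ENDMDL records")
  counts <- vapply(seq_along(starts), function(k) {
    blk <- lines[starts[k]:ends[k]]
    sum(grepl("^(ATOM|HETATM)", blk))
  }, integer(1))
  if (any(counts != counts[1L])) {
    bad <- which(counts != counts[1L])[1L]
    stop("model ", bad, " has ", counts[bad], " atoms, expected ",
         counts[1L])
  }
  topo <- .structure_from_lines(lines[starts[1L]:ends[1L]], model = 1L)
  frames <- lapply(seq_along(starts), function(k) {
    s <- .structure_from_lines(lines[starts[k]:ends[k]], model = 1L)
    s$coords
  })
  structure(list(topology = topo, frames = frames,
                 n_frames = length(frames)), class = "trajectory")
}

.structure_from_lines <- function(lines, model = 1L) {
  atom_ln <- grepl("^(ATOM|HETATM)", lines)
  if (!any(atom_ln)) stop("no ATOM/HETATM records found")
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- suppressWarnings(bio3d::read.pdb(tmp, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  element <- at$elesy
  blank <- is.na(element) | !nzchar(trimws(element))
  if (any(blank))
    element[blank] <- suppressWarnings(bio3d::atom2ele(at$elety[blank]))
  atoms <- data.frame(serial = at$eleno, atom = at$elety,
                      resname = at$resid, resno = at$resno,
                      chain = ifelse(is.na(at$chain), "", at$chain),
                      element = toupper(trimws(element)),
                      stringsAsFactors = FALSE)
  coords <- cbind(at$x, at$y, at$z)
  if (any(!is.finite(coords))) stop("non-finite coordinates in PDB input")
  colnames(coords) <- c("x", "y", "z")
  structure(list(atoms = atoms, coords = coords), class = "structure")
}

#' @export
print.structure <- function(x, ...) {
  cat("Structure: ", nrow(x$atoms), " atoms, ",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), " residues\n",
      sep = "")
  invisible(x)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory: ", x$n_frames, " frames x ", nrow(x$topology$atoms),
      " atoms\n", sep = "")
  invisible(x)
}

#' Select atoms of a structure
#'
#' Filters combine with AND; `NULL` filters are ignored.
#'
#' @param structure A `structure` (or a `trajectory`, whose topology is
#'   used).
#' @param resno Residue number(s).
#' @param resname Residue name(s).
#' @param atom Atom name(s) (e.g. `"CA"`).
#' @param chain Chain identifier(s).
#' @param element Element symbol(s).
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(structure, resno = NULL, resname = NULL,
                         atom = NULL, chain = NULL, element = NULL) {
  if (inherits(structure, "trajectory")) structure <- structure$topology
  stopifnot(inherits(structure, "structure"))
  at <- structure$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (!is.null(resname)) keep <- keep & at$resname %in% resname
  if (!is.null(atom)) keep <- keep & at$atom %in% atom
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(element)) keep <- keep & at$element %in% element
  which(keep)
}

# resolve a selection argument (indices or a spec list for select_atoms)
# to atom indices; optionally require exactly one atom
.resolve_selection <- function(traj, sel, single = FALSE, what = "selection") {
  topo <- if (inherits(traj, "trajectory")) traj$topology else traj
  idx <- if (is.numeric(sel)) as.integer(sel)
         else if (is.list(sel)) do.call(select_atoms, c(list(topo), sel))
         else stop(what, " must be atom indices or a named filter list")
  if (length(idx) == 0L) stop(what, " resolves to no atoms")
  if (any(idx < 1L | idx > nrow(topo$atoms)))
    stop(what, " contains out-of-range atom indices")
  if (single && length(idx) != 1L)
    stop(what, " must resolve to exactly one atom (got ", length(idx), ")")
  idx
}

# fixed-column PDB ATOM line (enough of the layout for round-tripping)
.pdb_atom_line <- function(serial, name, resname, chain, resno, xyz,
                           element) {
  name_fmt <- if (nchar(name) < 4L) sprintf(" %-3s", name)
              else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name_fmt, resname, chain, resno,
          xyz[1], xyz[2], xyz[3], element)
}

#' Write a trajectory as multi-model PDB text
#'
#' @param traj A `trajectory`.
#' @param file Optional output path.
#' @return Invisibly, the character vector of PDB lines.
#' @export
write_trajectory_pdb <- function(traj, file = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  at <- traj$topology$atoms
  lines <- unlist(lapply(seq_len(traj$n_frames), function(k) {
    xyz <- traj$frames[[k]]
    body <- vapply(seq_len(nrow(at)), function(i)
      .pdb_atom_line(at$serial[i], at$atom[i], at$resname[i],
                     ifelse(nzchar(at$chain[i]), at$chain[i], "A"),
                     at$resno[i], xyz[i, ], at$element[i]), character(1))
    c(sprintf("MODEL     %4d", k), body, "ENDMDL")
  }))
  lines <- c(lines, "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
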