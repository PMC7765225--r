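#' Molecular structure (one trajectory frame)
#'
#' A minimal container for one frame of a molecular system: atom labels and
#' Cartesian coordinates in Angstrom. Trajectories are plain lists of
#' `md_structure` objects sharing the same atoms.
#'
#' @param labels character vector of atom labels (element or PDB atom names,
#'   e.g. `"C"`, `"C1'"`, `"Na+"`); used to derive standard atomic masses.
#' @param coords numeric matrix with one row per atom and 3 columns (x, y, z)
#'   in Angstrom; all values must be finite.
#' @param frame_id integer frame identifier (>= 0).
#' @return An object of class `md_structure` with elements `labels`, `coords`
#'   and `frame_id`.
#' @examples
#' s <- md_structure(c("C", "O"), rbind(c(0, 0, 0), c(1.2, 0, 0)))
#' center_of_mass(s, 1:2)
#' @export
md_structure <- function(labels, coords, frame_id = 0L) {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3)
    stop("coords must be an n x 3 matrix", call. = FALSE)
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords)))
    stop("coords must be finite", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(coords))
    stop("length(labels) must equal nrow(coords)", call. = FALSE)
  dimnames(coords) <- NULL
  structure(list(labels = labels, coords = coords,
                 frame_id = as.integer(frame_id)),
            class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  cat("md_structure: ", nrow(x$coords), " atoms, frame ", x$frame_id, "\n",
      sep = "")
  invisible(x)
}

#' Per-atom masses for a structure
#'
#' Standard atomic masses looked up from the atom labels; a fragment map may
#' carry per-element overrides (see [fragment_map()]).
#'
#' @param structure an [md_structure()].
#' @param overrides optional named numeric vector mapping element symbols to
#'   masses, taking precedence over the built-in table.
#' @return numeric vector of masses (u), one per atom.
#' @export
atom_masses <- function(structure, overrides = NULL) {
  el <- .element_from_label(structure$labels)
  tab <- .atomic_masses
  if (!is.null(overrides)) {
    ov <- unlist(overrides)
    tab[toupper(names(ov))] <- as.numeric(ov)
  }
  m <- tab[el]
  if (anyNA(m))
    stop("no mass known for element(s): ",
         paste(unique(el[is.na(m)]), collapse = ", "),
         "; supply overrides", call. = FALSE)
  unname(m)
}

.check_trajectory <- function(traj) {
  if (!length(traj)) stop("empty trajectory", call. = FALSE)
  if (inherits(traj, "md_structure")) traj <- list(traj)
  n <- nrow(traj[[1]]$coords)
  for (s in traj) {
    if (!inherits(s, "md_structure"))
      stop("trajectory elements must be md_structure objects", call. = FALSE)
    if (nrow(s$coords) != n)
      stop("atom count varies across frames", call. = FALSE)
  }
  traj
}

#' Read a multi-model PDB trajectory
#'
#' Reads a MODEL/ENDMDL-delimited PDB file via [bio3d::read.pdb()] and
#' returns one [md_structure()] per model. Atom labels are the PDB atom
#' names.
#'
#' @param path path to a PDB file.
#' @return list of `md_structure` objects (frames numbered from 0).
#' @export
read_pdb_trajectory <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  labels <- pdb$atom$elety
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(i) {
    md_structure(labels, matrix(xyz[i, ], ncol = 3, byrow = TRUE),
                 frame_id = i - 1L)
  })
}

#' Read an XYZ trajectory
#'
#' Parses a concatenated-frame XYZ file (atom count line, free-form comment
#' line, then `element x y z` records, repeated per frame).
#'
#' @param path path to an XYZ file.
#' @return list of [md_structure()] objects (frames numbered from 0).
#' @export
read_xyz_trajectory <- function(path) {
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) > length(lines))]
  out <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop("XYZ parse error at line ", i, ": expected atom count",
           call. = FALSE)
    if (i + 1L + n > length(lines))
      stop("XYZ parse error: truncated frame starting at line ", i,
           call. = FALSE)
    block <- lines[(i + 2L):(i + 1L + n)]
    fields <- strsplit(trimws(block), "[[:space:]]+")
    if (any(lengths(fields) < 4))
      stop("XYZ parse error: malformed atom record near line ", i + 2L,
           call. = FALSE)
    labels <- vapply(fields, `[[`, "", 1L)
    xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    if (anyNA(xyz))
      stop("XYZ parse error: non-numeric coordinate near line ", i + 2L,
           call. = FALSE)
    out[[length(out) + 1L]] <- md_structure(labels, xyz, frame_id = frame)
    frame <- frame + 1L
    i <- i + 2L + n
  }
  if (!length(out)) stop("no frames found in ", path, call. = FALSE)
  out
}

#' Write an XYZ trajectory
#'
#' @param traj an [md_structure()] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  if (inherits(traj, "md_structure")) traj <- list(traj)
  traj <- .check_trajectory(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in traj) {
    writeLines(as.character(nrow(s$coords)), con)
    writeLines(sprintf("frame %d", s$frame_id), con)
    writeLines(sprintf("%s %.10f %.10f %.10f", s$labels,
                       s$coords[, 1], s$coords[, 2], s$coords[, 3]), con)
  }
  invisible(path)
}

#' Write a multi-model PDB trajectory
#'
#' Thin wrapper over [bio3d::write.pdb()]; frames become MODEL records.
#'
#' @inheritParams write_xyz_trajectory
#' @return `path`, invisibly.
#' @export
write_pdb_trajectory <- function(traj, path) {
  if (inherits(traj, "md_structure")) traj <- list(traj)
  traj <- .check_trajectory(traj)
  xyz <- do.call(rbind, lapply(traj, function(s) as.vector(t(s$coords))))
  s1 <- traj[[1]]
  bio3d::write.pdb(file = path, xyz = xyz,
                   elety = s1$labels,
                   resno = rep(1L, length(s1$labels)),
                   resid = rep("MOL", length(s1$labels)),
                   chain = rep("A", length(s1$labels)))
  invisible(path)
}

#' Read a trajectory in PDB or XYZ format
#'
#' @param path input file.
#' @param format `"pdb"`, `"xyz"` or `"auto"` (by file extension).
#' @return list of [md_structure()] objects.
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "ent")) "pdb" else "xyz"
  }
  switch(format,
         pdb = read_pdb_trajectory(path),
         xyz = read_xyz_trajectory(path))
}

#' Apply a rigid motion to a structure
#'
#' @param structure an [md_structure()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric translation (Angstrom).
#' @return the transformed `md_structure`.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  co <- structure$coords %*% t(rotation)
  co <- sweep(co, 2, translation, "+")
  md_structure(structure$labels, co, structure$frame_id)
}
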