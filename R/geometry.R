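#' Mass-weighted center of mass of an atom group
#'
#' @param structure an [md_structure()].
#' @param group integer vector of 1-based atom indices.
#' @param masses optional numeric vector of per-atom masses for the whole
#'   structure (defaults to standard atomic masses from the labels).
#' @return length-3 numeric vector (Angstrom).
#' @examples
#' s <- md_structure(c("C", "O"), rbind(c(0, 0, 0), c(1, 0, 0)))
#' center_of_mass(s, 1:2)  # pulled toward the heavier oxygen
#' @export
center_of_mass <- function(structure, group, masses = NULL) {
  stopifnot(inherits(structure, "md_structure"))
  group <- as.integer(group)
  if (!length(group)) stop("empty atom group", call. = FALSE)
  if (any(group < 1) || any(group > nrow(structure$coords)))
    stop("atom index out of range", call. = FALSE)
  if (is.null(masses)) masses <- atom_masses(structure)
  m <- masses[group]
  if (any(!is.finite(m)) || any(m <= 0))
    stop("masses must be positive", call. = FALSE)
  colSums(structure$coords[group, , drop = FALSE] * m) / sum(m)
}

#' Least-squares plane through a point set
#'
#' Fits the plane minimizing the sum of squared orthogonal distances (total
#' least squares via SVD of the centered coordinates). The normal sign is
#' fixed by `ref` when given (positive component along `ref`), otherwise by
#' making its first nonzero coordinate positive.
#'
#' @param points numeric matrix (>= 3 rows, 3 columns).
#' @param ref optional length-3 reference direction for the normal sign.
#' @return list with `centroid` and unit `normal`.
#' @export
fit_plane <- function(points, ref = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("plane fit needs at least 3 points",
                             call. = FALSE)
  centroid <- colMeans(points)
  x <- sweep(points, 2, centroid)
  sv <- svd(x)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    stop("degenerate geometry: points are collinear", call. = FALSE)
  normal <- sv$v[, 3]
  if (!is.null(ref) && .norm3(ref) > 1e-12) {
    if (sum(normal * ref) < 0) normal <- -normal
  } else {
    nz <- which(abs(normal) > 1e-12)[1]
    if (normal[nz] < 0) normal <- -normal
  }
  list(centroid = centroid, normal = normal)
}

#' Twist angle between intercalator and base-pair long axes
#'
#' Angle in degrees between the directed intercalator long axis
#' COM(ring_R1) -> COM(ring_R2) and the directed base-pair axis running from
#' the first to the second atom of `c1p_pair`. The angle is kept in
#' \[0, 180\]; supplementary angles are distinct poses (10 and 170 degrees
#' differ), and swapping the R1/R2 ordering maps the angle to 180 minus its
#' value.
#'
#' @param structure an [md_structure()].
#' @param fm a [fragment_map()].
#' @return twist angle in degrees.
#' @export
twist_angle <- function(structure, fm) {
  validate_fragment_map(fm, structure)
  masses <- atom_masses(structure, fm$masses)
  a <- center_of_mass(structure, fm$ring_R2, masses) -
    center_of_mass(structure, fm$ring_R1, masses)
  b <- structure$coords[fm$c1p_pair[2], ] - structure$coords[fm$c1p_pair[1], ]
  na <- .norm3(a); nb <- .norm3(b)
  if (na < 1e-8) stop("degenerate geometry: zero-length intercalator axis",
                      call. = FALSE)
  if (nb < 1e-8) stop("degenerate geometry: zero-length base-pair axis",
                      call. = FALSE)
  acos(.clamp(sum(a * b) / (na * nb), -1, 1)) * 180 / pi
}

#' Guanine-based stacking reference frame
#'
#' Builds the in-plane orthonormal frame used by the shift/slide
#' descriptors: the origin is the mass-weighted centroid of the guanine
#' six-membered ring; N1 points from the origin to the midpoint of the ring
#' C-C bond opposite the pyrrole ring, projected into the least-squares
#' guanine plane; N2 points toward the carbonyl group, projected into the
#' plane and Gram-Schmidt-orthogonalized against N1. The plane normal sign
#' points from guanine toward the intercalator.
#'
#' @inheritParams twist_angle
#' @return list with `origin`, unit vectors `n1`, `n2` and the plane
#'   `normal` (n1 and n2 orthogonal within 1e-10, both in the plane).
#' @export
stacking_frame <- function(structure, fm) {
  validate_fragment_map(fm, structure)
  masses <- atom_masses(structure, fm$masses)
  origin <- center_of_mass(structure, fm$guanine_ring6, masses)
  ref <- NULL
  if (!is.null(fm$ring_R1) && !is.null(fm$ring_R2)) {
    ref <- center_of_mass(structure, c(fm$ring_R1, fm$ring_R2), masses) -
      origin
  }
  pl <- fit_plane(structure$coords[fm$guanine_ring6, , drop = FALSE],
                  ref = ref)
  nrm <- pl$normal
  mid <- colMeans(structure$coords[fm$n1_bond, , drop = FALSE])
  n1 <- .unit(.project_plane(mid - origin, nrm), "N1 direction")
  carb <- center_of_mass(structure, fm$guanine_carbonyl, masses) - origin
  v2 <- .project_plane(carb, nrm)
  v2 <- v2 - sum(v2 * n1) * n1
  if (.norm3(v2) < 1e-8)
    stop("degenerate geometry: carbonyl direction parallel to N1",
         call. = FALSE)
  n2 <- .unit(v2, "N2 direction")
  list(origin = origin, n1 = n1, n2 = n2, normal = nrm)
}

#' Shift and slide distances of the intercalator rings
#'
#' For each outer intercalator ring, the separation between its center of
#' mass and the guanine ring centroid is projected onto the guanine plane;
#' the shift (N1) is the absolute component along the base-pair direction
#' and the slide (N2) the absolute component along the in-plane
#' perpendicular. Distances are reported as nonnegative values.
#'
#' @inheritParams twist_angle
#' @return named numeric vector `shift_R1`, `slide_R1`, `shift_R2`,
#'   `slide_R2` (Angstrom).
#' @export
shift_slide <- function(structure, fm) {
  fr <- stacking_frame(structure, fm)
  masses <- atom_masses(structure, fm$masses)
  comp <- function(ring) {
    d <- center_of_mass(structure, ring, masses) - fr$origin
    dp <- .project_plane(d, fr$normal)
    c(abs(sum(dp * fr$n1)), abs(sum(dp * fr$n2)))
  }
  r1 <- comp(fm$ring_R1); r2 <- comp(fm$ring_R2)
  c(shift_R1 = r1[1], slide_R1 = r1[2], shift_R2 = r2[1], slide_R2 = r2[2])
}

#' Stacking descriptors for every frame of a trajectory
#'
#' Computes twist, shift and slide for each frame. Frames on which the
#' geometry is degenerate are kept in the table with NA descriptors and the
#' error message in the `status` column; they are never silently dropped.
#'
#' @param traj list of [md_structure()] frames sharing the fragment map.
#' @param fm a [fragment_map()].
#' @return data.frame with columns `frame`, `twist_deg`, `shift_R1`,
#'   `slide_R1`, `shift_R2`, `slide_R2`, `status` ("ok" or the error).
#' @export
analyze_trajectory <- function(traj, fm) {
  traj <- .check_trajectory(traj)
  rows <- lapply(traj, function(s) {
    res <- tryCatch({
      tw <- twist_angle(s, fm)
      ss <- shift_slide(s, fm)
      data.frame(frame = s$frame_id, twist_deg = tw,
                 shift_R1 = ss[["shift_R1"]], slide_R1 = ss[["slide_R1"]],
                 shift_R2 = ss[["shift_R2"]], slide_R2 = ss[["slide_R2"]],
                 status = "ok", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(frame = s$frame_id, twist_deg = NA_real_,
                 shift_R1 = NA_real_, slide_R1 = NA_real_,
                 shift_R2 = NA_real_, slide_R2 = NA_real_,
                 status = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a stacking-descriptor table (TSV)
#'
#' @param desc data.frame from [analyze_trajectory()].
#' @param path file path.
#' @return `path` (writer) or the descriptor data.frame (reader).
#' @export
write_descriptors <- function(desc, path) {
  utils::write.table(desc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
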