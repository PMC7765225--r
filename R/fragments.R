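#' Fragment map: named atom groups for the stacking analysis
#'
#' Defines the atom groups the geometry descriptors rely on. All indices are
#' 1-based into the structure's atom list. Required groups:
#' \describe{
#'   \item{ring_R1, ring_R2}{the two outer benzene rings of the intercalator
#'     (anthraquinone); the directed long axis runs COM(R1) -> COM(R2).}
#'   \item{guanine_ring6}{the six-membered ring of the stacked guanine; its
#'     mass-weighted centroid and least-squares plane define the reference
#'     frame.}
#'   \item{c1p_pair}{exactly two atoms: the C1' sugar atoms of the base pair;
#'     the directed base-pair axis runs first -> second (guanine side first).}
#'   \item{guanine_carbonyl}{the carbonyl C and O of guanine, defining the
#'     slide direction before Gram-Schmidt orthogonalization.}
#'   \item{n1_bond}{exactly two atoms: the ring C-C bond opposite the pyrrole
#'     ring; its midpoint fixes the shift (base-pair) direction N1.}
#' }
#' Optional groups: `qm_region` (intercalator + guanine atoms, used for ion
#' distances) and `ions` (counter-ion positions). `masses` may override the
#' standard atomic mass of an element symbol.
#'
#' @param ring_R1,ring_R2,guanine_ring6,c1p_pair,guanine_carbonyl,n1_bond
#'   integer vectors of 1-based atom indices (see Description).
#' @param qm_region,ions optional integer index vectors.
#' @param masses optional named numeric vector of per-element mass overrides.
#' @return An object of class `fragment_map`.
#' @seealso [read_fragment_config()], [twist_angle()], [shift_slide()]
#' @export
fragment_map <- function(ring_R1, ring_R2, guanine_ring6, c1p_pair,
                         guanine_carbonyl, n1_bond,
                         qm_region = NULL, ions = NULL, masses = NULL) {
  as_idx <- function(x, nm) {
    if (is.null(x)) return(NULL)
    x <- as.integer(x)
    if (!length(x) || anyNA(x) || any(x < 1))
      stop("fragment group '", nm, "' must contain positive atom indices",
           call. = FALSE)
    x
  }
  fm <- list(
    ring_R1 = as_idx(ring_R1, "ring_R1"),
    ring_R2 = as_idx(ring_R2, "ring_R2"),
    guanine_ring6 = as_idx(guanine_ring6, "guanine_ring6"),
    c1p_pair = as_idx(c1p_pair, "c1p_pair"),
    guanine_carbonyl = as_idx(guanine_carbonyl, "guanine_carbonyl"),
    n1_bond = as_idx(n1_bond, "n1_bond"),
    qm_region = as_idx(qm_region, "qm_region"),
    ions = as_idx(ions, "ions"),
    masses = masses
  )
  if (length(fm$c1p_pair) != 2)
    stop("c1p_pair must contain exactly 2 atoms", call. = FALSE)
  if (length(fm$n1_bond) != 2)
    stop("n1_bond must contain exactly 2 atoms", call. = FALSE)
  if (length(fm$guanine_carbonyl) != 2)
    stop("guanine_carbonyl must contain exactly 2 atoms (C and O)",
         call. = FALSE)
  if (length(intersect(fm$ring_R1, fm$ring_R2)))
    stop("ring_R1 and ring_R2 must be disjoint", call. = FALSE)
  if (length(fm$guanine_ring6) < 3)
    stop("guanine_ring6 needs at least 3 atoms for a plane fit",
         call. = FALSE)
  class(fm) <- "fragment_map"
  fm
}

#' @export
print.fragment_map <- function(x, ...) {
  grp <- setdiff(names(x), "masses")
  for (g in grp)
    if (!is.null(x[[g]]))
      cat(sprintf("%-17s %s\n", g, paste(x[[g]], collapse = " ")))
  invisible(x)
}

#' Validate a fragment map against a structure
#'
#' Checks that every index is within the atom count.
#'
#' @param fm a [fragment_map()].
#' @param structure an [md_structure()].
#' @return `fm`, invisibly; errors on out-of-range indices.
#' @export
validate_fragment_map <- function(fm, structure) {
  stopifnot(inherits(fm, "fragment_map"), inherits(structure, "md_structure"))
  n <- nrow(structure$coords)
  for (g in setdiff(names(fm), "masses")) {
    idx <- fm[[g]]
    if (!is.null(idx) && any(idx > n))
      stop("fragment group '", g, "' has atom index out of range (n = ",
           n, ")", call. = FALSE)
  }
  invisible(fm)
}

#' Read a fragment configuration file (YAML)
#'
#' The file maps group names to lists of 1-based atom indices, with an
#' optional `masses` mapping of element symbol to mass, e.g.
#' ```yaml
#' ring_R1: [10, 11, 12, 13, 14, 15]
#' c1p_pair: [1, 2]
#' masses: {NA: 22.99}
#' ```
#'
#' @param path path to a YAML file.
#' @return a validated [fragment_map()].
#' @export
read_fragment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("ring_R1", "ring_R2", "guanine_ring6", "c1p_pair",
                "guanine_carbonyl", "n1_bond")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("fragment config ", path, " is missing group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  fragment_map(ring_R1 = cfg$ring_R1, ring_R2 = cfg$ring_R2,
               guanine_ring6 = cfg$guanine_ring6, c1p_pair = cfg$c1p_pair,
               guanine_carbonyl = cfg$guanine_carbonyl,
               n1_bond = cfg$n1_bond, qm_region = cfg$qm_region,
               ions = cfg$ions, masses = cfg$masses)
}

#' Write a fragment configuration file (YAML)
#'
#' @param fm a [fragment_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragment_config <- function(fm, path) {
  stopifnot(inherits(fm, "fragment_map"))
  out <- Filter(Negate(is.null), unclass(fm))
  yaml::write_yaml(out, path)
  invisible(path)
}
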