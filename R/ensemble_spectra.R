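.ok_rows <- function(desc) {
  if (!nrow(desc)) stop("empty descriptor table", call. = FALSE)
  ok <- desc[desc$status == "ok" & !is.na(desc$class), , drop = FALSE]
  if (!nrow(ok)) stop("no successfully characterized states", call. = FALSE)
  ok
}

#' Class contributions to the density of states
#'
#' Count-weighted percentage of each excited-state class (every state
#' contributes equally, as in a density of states).
#'
#' @param desc descriptor table from [analyze_records()].
#' @return named numeric vector of percentages over
#'   [state_classes()], summing to 100; attribute `n` holds the state count.
#' @export
class_fractions <- function(desc) {
  ok <- .ok_rows(desc)
  tab <- table(factor(ok$class, levels = state_classes()))
  out <- 100 * as.numeric(tab) / nrow(ok)
  names(out) <- state_classes()
  attr(out, "n") <- nrow(ok)
  out
}

#' Class contributions to the absorption spectrum
#'
#' Oscillator-strength-weighted percentages: each state is weighted by its
#' oscillator strength, so dark states (e.g. most charge-transfer states)
#' lose weight relative to their density-of-states share.
#'
#' @param desc descriptor table from [analyze_records()] (carries the `osc`
#'   column of the state records).
#' @return named numeric vector of percentages summing to 100; attribute
#'   `n` holds the state count.
#' @export
intensity_fractions <- function(desc) {
  ok <- .ok_rows(desc)
  tot <- sum(ok$osc)
  if (tot <= 0)
    stop("total oscillator strength is zero", call. = FALSE)
  w <- vapply(state_classes(),
              function(cl) sum(ok$osc[ok$class == cl]), numeric(1))
  out <- 100 * w / tot
  attr(out, "n") <- nrow(ok)
  out
}

#' Energy grid with Gaussian broadening parameters
#'
#' @param e_min,e_max grid limits (eV, `e_min < e_max`).
#' @param n_points number of grid points (>= 2).
#' @param fwhm Gaussian full width at half maximum (eV, > 0).
#' @return list of class `energy_grid`.
#' @export
energy_grid <- function(e_min, e_max, n_points = 501, fwhm = 0.3) {
  if (!(e_min < e_max)) stop("need e_min < e_max", call. = FALSE)
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  if (!(fwhm > 0)) stop("fwhm must be positive", call. = FALSE)
  structure(list(e_min = e_min, e_max = e_max,
                 n_points = as.integer(n_points), fwhm = fwhm),
            class = "energy_grid")
}

#' Broadened decomposition of DOS or absorption spectrum
#'
#' Each characterized state contributes a Gaussian of the grid's FWHM
#' centered at its energy — unit area for `weighting = "count"` (density of
#' states) or area equal to its oscillator strength for
#' `weighting = "oscillator"` (absorption spectrum) — accumulated into the
#' curve of its class. Class curves sum pointwise to the total curve, and
#' both count- and oscillator-weighted class percentages are reported.
#'
#' @param desc descriptor table from [analyze_records()].
#' @param grid an [energy_grid()]; a warning is issued if it does not cover
#'   the energy range of the states.
#' @param weighting `"count"` (DOS) or `"oscillator"` (spectrum).
#' @return object of class `decomposition`: list with `energy` (grid
#'   vector), `curves` (data.frame `total` + one column per class),
#'   `weighting`, `percent_dos`, `percent_abs`, `fwhm`, `n`.
#' @export
broadened_decomposition <- function(desc, grid = energy_grid(
                                      min(desc$energy_ev) - 1,
                                      max(desc$energy_ev) + 1),
                                    weighting = c("count", "oscillator")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(grid, "energy_grid"))
  ok <- .ok_rows(desc)
  if (min(ok$energy_ev) < grid$e_min || max(ok$energy_ev) > grid$e_max)
    warning("energy grid does not cover the full state energy range")
  e <- seq(grid$e_min, grid$e_max, length.out = grid$n_points)
  sigma <- grid$fwhm / (2 * sqrt(2 * log(2)))
  w <- if (weighting == "count") rep(1, nrow(ok)) else ok$osc
  curves <- sapply(state_classes(), function(cl) {
    sel <- which(ok$class == cl)
    if (!length(sel)) return(numeric(length(e)))
    rowSums(vapply(sel, function(i) {
      w[i] * dnorm(e, mean = ok$energy_ev[i], sd = sigma)
    }, numeric(length(e))))
  })
  curves <- as.data.frame(curves)
  curves$total <- rowSums(curves)
  structure(list(energy = e, curves = curves, weighting = weighting,
                 percent_dos = class_fractions(desc),
                 percent_abs = intensity_fractions(desc),
                 fwhm = grid$fwhm, n = nrow(ok)),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat("decomposition of", x$n, "states (", x$weighting, "weighting )\n")
  cat("  DOS %:     ", paste(sprintf("%s %.1f", state_classes(),
                                     x$percent_dos), collapse = ", "), "\n")
  cat("  spectrum %:", paste(sprintf("%s %.1f", state_classes(),
                                     x$percent_abs), collapse = ", "), "\n")
  invisible(x)
}

#' Write the decomposition curves as TSV
#'
#' Columns: `energy_ev total monomer exciton excimer ct`.
#'
#' @param dec a `decomposition` from [broadened_decomposition()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_decomposition <- function(dec, path) {
  stopifnot(inherits(dec, "decomposition"))
  df <- data.frame(energy_ev = dec$energy,
                   total = dec$curves$total,
                   monomer = dec$curves$monomer,
                   exciton = dec$curves$exciton,
                   excimer = dec$curves$excimer,
                   ct = dec$curves$charge_transfer)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-dimensional CTN/DL_av probability map
#'
#' Histogram of the joint (DL_av, CTN) distribution, normalized to unit
#' total mass. When the bin edges include the classification thresholds,
#' the mass of each threshold quadrant reproduces the class fractions
#' (up to states sitting exactly on the upper CTN cut).
#'
#' @param desc descriptor table from [analyze_records()].
#' @param dl_breaks,ctn_breaks bin edges; defaults are 0.05-wide bins over
#'   \[1, N_frag\] and \[0, 1\].
#' @return list with `dl_breaks`, `ctn_breaks` and `mass` (matrix, DL bins
#'   in rows, CTN bins in columns, summing to 1).
#' @export
ctn_dlav_map <- function(desc, dl_breaks = NULL, ctn_breaks = NULL) {
  ok <- .ok_rows(desc)
  n_frag <- attr(desc, "n_frag")
  if (is.null(n_frag)) n_frag <- max(2, ceiling(max(ok$dl_av)))
  if (is.null(dl_breaks)) dl_breaks <- seq(1, n_frag, by = 0.05)
  if (is.null(ctn_breaks)) ctn_breaks <- seq(0, 1, by = 0.05)
  nb_d <- length(dl_breaks) - 1L
  nb_c <- length(ctn_breaks) - 1L
  di <- findInterval(ok$dl_av, dl_breaks, rightmost.closed = TRUE)
  ci <- findInterval(ok$ctn, ctn_breaks, rightmost.closed = TRUE)
  keep <- di >= 1L & di <= nb_d & ci >= 1L & ci <= nb_c
  if (!any(keep)) stop("no states fall inside the bin ranges", call. = FALSE)
  di <- di[keep]; ci <- ci[keep]
  mass <- matrix(0, nb_d, nb_c)
  for (k in seq_along(di))
    mass[di[k], ci[k]] <- mass[di[k], ci[k]] + 1
  mass <- mass / sum(keep)
  list(dl_breaks = dl_breaks, ctn_breaks = ctn_breaks, mass = mass)
}

#' POS distributions of the hole and the excited electron
#'
#' Unit-mass histograms of the hole position (POS_i) and the
#' excited-electron position (POS_f), optionally restricted to one state
#' class. An empty class yields empty histograms with `empty = TRUE`.
#'
#' @param desc descriptor table from [analyze_records()].
#' @param class one of [state_classes()] or `"all"`.
#' @param breaks bin edges over \[1, N_frag\]; default 0.05-wide bins.
#' @return list with `class`, `n`, `empty` flag and data.frames `pos_i`,
#'   `pos_f` (`lo`, `hi`, `mass`).
#' @export
pos_distributions <- function(desc, class = "all", breaks = NULL) {
  stopifnot(class %in% c(state_classes(), "all"))
  ok <- .ok_rows(desc)
  if (class != "all") ok <- ok[ok$class == class, , drop = FALSE]
  n_frag <- attr(desc, "n_frag")
  if (is.null(n_frag)) n_frag <- 2
  if (is.null(breaks)) breaks <- seq(1, n_frag, by = 0.05)
  hist1 <- function(x) {
    df <- data.frame(lo = breaks[-length(breaks)], hi = breaks[-1])
    if (!length(x)) { df$mass <- 0; return(df) }
    idx <- findInterval(x, breaks, rightmost.closed = TRUE)
    df$mass <- tabulate(idx, nbins = length(breaks) - 1L) / length(x)
    df
  }
  list(class = class, n = nrow(ok), empty = nrow(ok) == 0,
       pos_i = hist1(ok$pos_i), pos_f = hist1(ok$pos_f))
}

#' Distance from the QM region to the nearest counter-ion
#'
#' Minimum Euclidean distance between the mass-weighted center of the
#' `qm_region` group (intercalator + guanine) and any atom of the `ions`
#' group.
#'
#' @param structure an [md_structure()].
#' @param fm a [fragment_map()] with non-empty `qm_region` and `ions`.
#' @return distance in Angstrom.
#' @export
nearest_ion_distance <- function(structure, fm) {
  validate_fragment_map(fm, structure)
  if (is.null(fm$ions) || !length(fm$ions))
    stop("fragment map defines no ions", call. = FALSE)
  if (is.null(fm$qm_region) || !length(fm$qm_region))
    stop("fragment map defines no qm_region", call. = FALSE)
  com <- center_of_mass(structure, fm$qm_region,
                        atom_masses(structure, fm$masses))
  d <- sweep(structure$coords[fm$ions, , drop = FALSE], 2, com)
  min(sqrt(rowSums(d * d)))
}

#' Binned trend of a descriptor against a coordinate
#'
#' Per-bin arithmetic mean (e.g. mean CTN in 1-Angstrom ion-distance bins).
#' Values on a bin edge join the upper bin; the last bin is closed. Empty
#' bins carry `NA` means and count 0.
#'
#' @param x coordinate values (e.g. nearest-ion distance, Angstrom).
#' @param y descriptor values, same length as `x`.
#' @param bin_edges increasing numeric vector of bin edges; default 1-A
#'   bins over \[0, 20\].
#' @return data.frame with `lo`, `hi`, `mean`, `count`.
#' @export
binned_trend <- function(x, y, bin_edges = seq(0, 20, by = 1)) {
  if (length(x) != length(y) || !length(x))
    stop("x and y must be non-empty and of equal length", call. = FALSE)
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing", call. = FALSE)
  idx <- findInterval(x, bin_edges, rightmost.closed = TRUE)
  nb <- length(bin_edges) - 1L
  inside <- idx >= 1 & idx <= nb
  count <- tabulate(idx[inside], nbins = nb)
  mean_y <- rep(NA_real_, nb)
  for (b in unique(idx[inside]))
    mean_y[b] <- mean(y[inside][idx[inside] == b])
  data.frame(lo = bin_edges[-length(bin_edges)], hi = bin_edges[-1],
             mean = mean_y, count = count)
}

#' Compare class fractions across embedding models
#'
#' Aligns the density-of-states class fractions of two or more descriptor
#' tables (e.g. full solvated system, strand-embedded, vacuum) and reports
#' differences against the first model.
#'
#' @param desc_tables named list (>= 2 entries) of descriptor tables from
#'   [analyze_records()].
#' @return list with `fractions` (models x classes matrix, rows summing to
#'   100), `differences` (same shape, relative to the first model) and `n`
#'   per model.
#' @export
compare_models <- function(desc_tables) {
  if (!is.list(desc_tables) || length(desc_tables) < 2 ||
      is.null(names(desc_tables)) || any(!nzchar(names(desc_tables))))
    stop("desc_tables must be a named list with at least 2 models",
         call. = FALSE)
  fr <- t(vapply(desc_tables, function(d) as.numeric(class_fractions(d)),
                 numeric(4)))
  colnames(fr) <- state_classes()
  diffs <- sweep(fr, 2, fr[1, ])
  list(fractions = fr, differences = diffs,
       n = vapply(desc_tables, function(d) attr(class_fractions(d), "n"),
                  numeric(1)))
}
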