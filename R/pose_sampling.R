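#' The four canonical twist-angle configuration windows
#'
#' Two symmetric (strongly stacked) and two rotated poses of the
#' intercalator: (0,30), (30,60), (120,150) and (150,180) degrees.
#' Intervals are half-open \[lo, hi); 180 degrees is included in
#' `symmetric_2`. Twists in \[60, 120) belong to no window.
#'
#' @return data.frame with columns `label`, `lo`, `hi` (degrees).
#' @export
configuration_windows <- function() {
  data.frame(
    label = c("symmetric_1", "rotated_1", "rotated_2", "symmetric_2"),
    lo = c(0, 30, 120, 150),
    hi = c(30, 60, 150, 180),
    stringsAsFactors = FALSE
  )
}

#' Assign twist angles to configuration windows
#'
#' @param twist numeric vector of twist angles in degrees, all in
#'   \[0, 180\].
#' @return character vector of window labels; `NA` for the gap region
#'   \[60, 120).
#' @examples
#' assign_window(c(15, 45, 90, 155, 180))
#' @export
assign_window <- function(twist) {
  twist <- as.numeric(twist)
  if (any(!is.finite(twist)) || any(twist < 0 | twist > 180))
    stop("twist angles must lie in [0, 180] degrees", call. = FALSE)
  w <- configuration_windows()
  out <- rep(NA_character_, length(twist))
  for (i in seq_len(nrow(w))) {
    inw <- twist >= w$lo[i] & (twist < w$hi[i] | (w$hi[i] == 180 &
                                                    twist == 180))
    out[inw] <- w$label[i]
  }
  out
}

#' Histogram density of twist angles
#'
#' Left-closed bins of the given width covering \[0, 180\] (a value on a bin
#' edge belongs to the upper bin; 180 falls in the last bin). Densities
#' integrate to 1.
#'
#' @param twists numeric vector of angles in \[0, 180\] (degrees).
#' @param bin_width bin width in degrees (> 0; default 2).
#' @return data.frame with columns `lo`, `hi`, `mid`, `count`, `density`.
#' @export
twist_distribution <- function(twists, bin_width = 2) {
  if (!length(twists)) stop("empty twist vector", call. = FALSE)
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be positive", call. = FALSE)
  if (any(twists < 0 | twists > 180))
    stop("twist angles must lie in [0, 180] degrees", call. = FALSE)
  edges <- seq(0, 180, by = bin_width)
  if (max(edges) < 180) edges <- c(edges, 180)
  idx <- findInterval(twists, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  count <- tabulate(idx, nbins = nb)
  width <- diff(edges)
  data.frame(lo = edges[-length(edges)], hi = edges[-1],
             mid = (edges[-length(edges)] + edges[-1]) / 2,
             count = count,
             density = count / (length(twists) * width))
}

.resolve_window <- function(window) {
  w <- configuration_windows()
  if (is.character(window)) {
    if (!window %in% w$label)
      stop("unknown window label '", window, "'", call. = FALSE)
    i <- match(window, w$label)
    list(label = window, lo = w$lo[i], hi = w$hi[i])
  } else if (is.numeric(window) && length(window) == 2) {
    if (window[1] >= window[2])
      stop("window must satisfy lo < hi", call. = FALSE)
    list(label = sprintf("custom[%g,%g)", window[1], window[2]),
         lo = window[1], hi = window[2])
  } else {
    stop("window must be a label or a numeric c(lo, hi)", call. = FALSE)
  }
}

#' Metropolis Monte Carlo snapshot selection
#'
#' Selects `n` frames whose twist angles reproduce the in-window empirical
#' twist distribution of the pool (the molecular-dynamics ensemble is
#' already Boltzmann-weighted, so the empirical distribution is the
#' Metropolis target). A Markov chain runs over the histogram bins of the
#' in-window twists: a bin is proposed uniformly at random and accepted with
#' probability `min(1, mass(proposed)/mass(current))`; after burn-in, the
#' current bin is recorded at every `thin`-th step (a rejected proposal
#' leaves the chain in place, as usual) and one pool frame from that bin is
#' emitted. Selection is without replacement when the pool
#' holds at least `n` frames, with replacement (flagged) otherwise. The
#' selection is deterministic given `seed`.
#'
#' @param twists numeric vector of per-frame twist angles (degrees); the
#'   index into this vector is the frame index reported back.
#' @param window a window label from [configuration_windows()] or
#'   `c(lo, hi)` in degrees.
#' @param n number of frames to select (>= 1).
#' @param seed integer RNG seed.
#' @param bin_width histogram bin width in degrees for the Metropolis
#'   target (default 2).
#' @param burn_in number of proposals discarded before recording; default
#'   `max(1000, 50 * n_bins)`.
#' @param thin record at every `thin`-th chain step after burn-in
#'   (default 5).
#' @return object of class `sample_selection`: list with `window`, `lo`,
#'   `hi`, `frame_indices`, `twists`, `n_requested`, `seed`,
#'   `with_replacement`.
#' @export
metropolis_select <- function(twists, window, n, seed, bin_width = 2,
                              burn_in = NULL, thin = 5L) {
  stopifnot(n >= 1)
  win <- .resolve_window(window)
  in_win <- twists >= win$lo &
    (twists < win$hi | (win$hi == 180 & twists == 180))
  pool <- which(in_win)
  if (!length(pool))
    stop("no frames inside window ", win$label, call. = FALSE)
  edges <- seq(win$lo, win$hi, by = bin_width)
  if (max(edges) < win$hi) edges <- c(edges, win$hi)
  nb <- length(edges) - 1L
  bin_of <- findInterval(twists[pool], edges, rightmost.closed = TRUE)
  counts <- tabulate(bin_of, nbins = nb)
  by_bin <- split(pool, factor(bin_of, levels = seq_len(nb)))
  replace <- length(pool) < n
  if (is.null(burn_in)) burn_in <- max(1000L, 50L * nb)
  sel <- integer(n)
  n_sel <- 0L
  withr::with_seed(seed, {
    taken <- logical(length(twists))
    cur <- sample(which(counts > 0), 1L)
    it <- 0L
    max_it <- burn_in + 5000L * n * thin
    while (n_sel < n && it < max_it) {
      it <- it + 1L
      prop <- sample.int(nb, 1L)
      if (counts[prop] > 0L && runif(1) <= counts[prop] / counts[cur])
        cur <- prop
      if (it > burn_in && (it - burn_in) %% thin == 0L) {
        cand <- by_bin[[cur]]
        if (replace) {
          n_sel <- n_sel + 1L
          sel[n_sel] <- cand[sample.int(length(cand), 1L)]
        } else {
          free <- cand[!taken[cand]]
          if (length(free)) {
            f <- free[sample.int(length(free), 1L)]
            taken[f] <- TRUE
            n_sel <- n_sel + 1L
            sel[n_sel] <- f
          }
        }
      }
    }
  })
  if (n_sel < n)
    stop("Metropolis chain did not collect ", n, " frames; pool too small ",
         "or target too concentrated", call. = FALSE)
  structure(list(window = win$label, lo = win$lo, hi = win$hi,
                 frame_indices = sel, twists = twists[sel],
                 n_requested = as.integer(n), seed = as.integer(seed),
                 with_replacement = replace),
            class = "sample_selection")
}

#' @export
print.sample_selection <- function(x, ...) {
  cat("sample_selection:", length(x$frame_indices), "frames from window",
      x$window,
      if (x$with_replacement) "(with replacement)" else "", "\n")
  invisible(x)
}

#' Write a snapshot selection as TSV (`window frame seed`)
#'
#' @param sel a `sample_selection` from [metropolis_select()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path) {
  stopifnot(inherits(sel, "sample_selection"))
  df <- data.frame(window = sel$window, frame = sel$frame_indices,
                   seed = sel$seed)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
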