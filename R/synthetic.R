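# Idealized planar templates. Geometry descriptors depend only on labeled
# centers of mass, the ring plane and anchor atoms, so regular polygons with
# the required labeled substructures make the construction an exact oracle.

# guanine-like template in the z = 0 plane:
#   atoms 1-6: six-membered ring (regular hexagon, radius 1.4 A, vertices at
#     30, 90, ..., 330 degrees; all carbon, so the ring COM is the origin)
#   atom 7:   carbonyl O outward from the ring C at 90 degrees
#   atoms 8-9: the two C1' anchor atoms; their directed axis (8 -> 9) is +x
# labeled bonds: n1_bond = ring atoms at -30/+30 degrees (midpoint on +x)
.guanine_template <- function() {
  ang <- c(30, 90, 150, 210, 270, 330) * pi / 180
  ring <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  carbonyl_o <- c(0, 1.4 + 1.23, 0)
  c1p <- rbind(c(-3.8, -1.2, 0), c(3.8, -1.2, 0))
  coords <- rbind(ring, carbonyl_o, c1p)
  labels <- c(rep("C", 6), "O", "C1'", "C1'")
  list(coords = coords, labels = labels,
       guanine_ring6 = 1:6,
       guanine_carbonyl = c(2L, 7L),   # ring C at 90 deg + its O
       n1_bond = c(1L, 6L),            # vertices at 30 and 330 deg
       c1p_pair = c(8L, 9L))
}

# anthraquinone-like tricyclic template in its local z = 0 plane: two outer
# hexagons (R1 left, R2 right) with the R1 ring COM at the local origin and
# the long axis COM(R1) -> COM(R2) along +x.
.aq_template <- function() {
  ang <- seq(0, 300, by = 60) * pi / 180
  hexagon <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  r1 <- hexagon
  r2 <- sweep(hexagon, 2, c(5.6, 0, 0), "+")
  list(coords = rbind(r1, r2), labels = rep("C", 12),
       ring_R1 = 1:6, ring_R2 = 7:12)
}

#' Build a synthetic stacked intercalator/guanine dimer
#'
#' Constructs an idealized planar guanine-like template (labeled
#' six-membered ring, carbonyl arm, pyrrole-opposite C-C bond and C1'
#' anchors) and an intercalator-like template with labeled outer rings R1
#' and R2. The intercalator is rotated by `twist` about the guanine plane
#' normal (about its R1 ring center) and placed with its R1 ring center at
#' `shift` along N1, `slide` along N2 and `rise` above the guanine plane.
#' With zero jitter the geometry module recovers (twist, shift, slide)
#' exactly, which makes this constructor the round-trip oracle for the
#' stacking descriptors.
#'
#' @param twist twist angle in degrees, in \[0, 180\].
#' @param shift,slide in-plane displacements (Angstrom, >= 0).
#' @param rise normal separation between the planes (Angstrom, > 0;
#'   default 3.4, a typical stacking distance).
#' @param jitter_sigma per-atom isotropic Gaussian noise (Angstrom, >= 0).
#' @param seed RNG seed (required when `jitter_sigma > 0`).
#' @param frame_id frame identifier for the returned structure.
#' @param ion_positions optional matrix of counter-ion coordinates (rows of
#'   x, y, z) appended as Na atoms and registered in the `ions` group.
#' @return list with `structure` (an [md_structure()]) and `fm`
#'   (a [fragment_map()]).
#' @examples
#' d <- make_stacked_dimer(twist = 47, shift = 2, slide = 1.5)
#' twist_angle(d$structure, d$fm)
#' shift_slide(d$structure, d$fm)
#' @export
make_stacked_dimer <- function(twist, shift = 0, slide = 0, rise = 3.4,
                               jitter_sigma = 0, seed = NULL, frame_id = 0L,
                               ion_positions = NULL) {
  stopifnot(rise > 0, jitter_sigma >= 0, twist >= 0, twist <= 180)
  g <- .guanine_template()
  a <- .aq_template()
  rot <- .rotation_about(c(0, 0, 1), twist)
  aq <- a$coords %*% t(rot)
  aq <- sweep(aq, 2, c(shift, slide, rise), "+")
  n_g <- nrow(g$coords)
  coords <- rbind(g$coords, aq)
  labels <- c(g$labels, a$labels)
  ions <- NULL
  if (!is.null(ion_positions)) {
    ion_positions <- matrix(as.numeric(ion_positions), ncol = 3)
    ions <- nrow(coords) + seq_len(nrow(ion_positions))
    coords <- rbind(coords, ion_positions)
    labels <- c(labels, rep("Na", nrow(ion_positions)))
  }
  if (jitter_sigma > 0) {
    if (is.null(seed)) stop("seed required when jitter_sigma > 0",
                            call. = FALSE)
    coords <- withr::with_seed(seed, {
      coords + matrix(rnorm(length(coords), sd = jitter_sigma),
                      nrow(coords), 3)
    })
  }
  fm <- fragment_map(
    ring_R1 = n_g + a$ring_R1, ring_R2 = n_g + a$ring_R2,
    guanine_ring6 = g$guanine_ring6, c1p_pair = g$c1p_pair,
    guanine_carbonyl = g$guanine_carbonyl, n1_bond = g$n1_bond,
    qm_region = c(seq_len(n_g), n_g + seq_len(nrow(a$coords))),
    ions = ions
  )
  list(structure = md_structure(labels, coords, frame_id = frame_id),
       fm = fm)
}

# one draw from a Gaussian truncated to [lo, hi]
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' Synthetic pose trajectory across the configuration windows
#'
#' Draws per-frame twist angles from a mixture over the four configuration
#' windows (truncated Gaussians centered in each window) together with small
#' random shift/slide displacements, builds a stacked dimer for every frame
#' and records the ground-truth window, twist, shift and slide per frame.
#'
#' @param weights nonnegative mixture weights over the four windows of
#'   [configuration_windows()], summing to 1.
#' @param n_frames number of frames (>= 1).
#' @param seed integer RNG seed; the trajectory is deterministic given the
#'   seed.
#' @param twist_sd within-window twist standard deviation (degrees,
#'   default 8).
#' @param shift_max,slide_max upper bounds of the uniform shift/slide draws
#'   (Angstrom).
#' @param jitter_sigma per-atom Gaussian coordinate noise (Angstrom).
#' @return list with `trajectory` (list of [md_structure()]), `fm` (shared
#'   [fragment_map()]) and `truth` (data.frame `frame`, `window`, `twist`,
#'   `shift`, `slide`).
#' @export
make_pose_trajectory <- function(weights = rep(0.25, 4), n_frames, seed,
                                 twist_sd = 8, shift_max = 2,
                                 slide_max = 1.5, jitter_sigma = 0) {
  stopifnot(length(weights) == 4, all(weights >= 0), n_frames >= 1)
  if (abs(sum(weights) - 1) > 1e-8)
    stop("window weights must sum to 1", call. = FALSE)
  w <- configuration_windows()
  out <- withr::with_seed(seed, {
    win <- sample.int(4, n_frames, replace = TRUE, prob = weights)
    twist <- .rtruncnorm(n_frames, mean = (w$lo[win] + w$hi[win]) / 2,
                         sd = twist_sd, lo = w$lo[win], hi = w$hi[win])
    # keep strictly inside the half-open window
    twist <- pmin(twist, w$hi[win] - 1e-9)
    shift <- runif(n_frames, 0, shift_max)
    slide <- runif(n_frames, 0, slide_max)
    jseed <- if (jitter_sigma > 0)
      sample.int(.Machine$integer.max, n_frames) else rep(NA_integer_,
                                                          n_frames)
    list(win = win, twist = twist, shift = shift, slide = slide,
         jseed = jseed)
  })
  traj <- vector("list", n_frames)
  fm <- NULL
  for (i in seq_len(n_frames)) {
    d <- make_stacked_dimer(out$twist[i], out$shift[i], out$slide[i],
                            jitter_sigma = jitter_sigma,
                            seed = if (jitter_sigma > 0) out$jseed[i],
                            frame_id = i - 1L)
    traj[[i]] <- d$structure
    if (is.null(fm)) fm <- d$fm
  }
  list(trajectory = traj, fm = fm,
       truth = data.frame(frame = seq_len(n_frames) - 1L,
                          window = w$label[out$win],
                          twist = out$twist, shift = out$shift,
                          slide = out$slide, stringsAsFactors = FALSE))
}

.archetype_omega <- function(class, ct_direction = c("2to1", "1to2")) {
  ct_direction <- match.arg(ct_direction)
  ct <- if (ct_direction == "2to1") {
    matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE)  # hole on 2, electron on 1
  } else {
    matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  }
  switch(class,
         monomer = matrix(c(1, 0, 0, 0), 2, 2),
         exciton = diag(c(0.5, 0.5)),
         charge_transfer = ct,
         excimer = 0.5 * matrix(c(1, 0, 0, 0), 2, 2) + 0.5 * ct,
         stop("unknown class '", class, "'", call. = FALSE))
}

#' Sample a synthetic Omega matrix of a given class
#'
#' Starts from the pure archetype of the requested class (monomer localized
#' on fragment 1, exciton with equal diagonal weight, charge transfer with
#' all weight on one off-diagonal element, excimer as an equal monomer/CT
#' mixture), blends it with a random nonnegative matrix:
#' `(1 - mixing_noise) * archetype + mixing_noise * noise`, renormalizes,
#' and (when `guarantee_label` is set) rejects draws that no longer classify
#' as the requested label under the given thresholds.
#'
#' @param class one of [state_classes()].
#' @param mixing_noise blending weight in \[0, 1) of the random component.
#' @param ct_direction `"2to1"` (hole on fragment 2, electron on fragment 1)
#'   or `"1to2"`; also orients the CT component of excimers.
#' @param seed optional RNG seed (draws are deterministic given the seed).
#' @param guarantee_label reject-and-retry until the draw classifies as
#'   `class` (default TRUE).
#' @param thresholds a [class_thresholds()].
#' @param max_tries rejection budget before failing (default 1000).
#' @return a normalized 2x2 Omega matrix (see [normalize_omega()]).
#' @export
sample_omega <- function(class, mixing_noise = 0,
                         ct_direction = c("2to1", "1to2"), seed = NULL,
                         guarantee_label = TRUE,
                         thresholds = class_thresholds(),
                         max_tries = 1000L) {
  ct_direction <- match.arg(ct_direction)
  stopifnot(mixing_noise >= 0, mixing_noise < 1)
  arch <- .archetype_omega(class, ct_direction)
  draw <- function() {
    if (mixing_noise == 0) return(normalize_omega(arch))
    noise <- matrix(runif(4), 2, 2)
    normalize_omega((1 - mixing_noise) * arch +
                      mixing_noise * noise / sum(noise))
  }
  body <- function() {
    for (k in seq_len(max_tries)) {
      om <- draw()
      if (!guarantee_label ||
          classify_state(dl_av(om), ctn(om), thresholds) == class)
        return(om)
      if (mixing_noise == 0) break
    }
    stop("could not draw an Omega matrix classifying as '", class,
         "' within ", max_tries, " attempts; mixing_noise too large",
         call. = FALSE)
  }
  if (is.null(seed)) body() else withr::with_seed(seed, body())
}

#' Synthetic excited-state ensemble with known class labels
#'
#' Emulates an ensemble of vertical excitations over many snapshots: each
#' record draws its class from `class_fractions`, its Omega matrix from
#' [sample_omega()], its energy uniformly on `energy_range` and its
#' oscillator strength from a per-class log-normal model in which
#' charge-transfer states are dark (mean suppressed by `ct_osc_scale`,
#' default 1% of the bright classes).
#'
#' @param class_fractions nonnegative weights over [state_classes()]
#'   summing to 1 (default c(0.42, 0.03, 0.25, 0.30), a realistic DOS
#'   composition for a stacked intercalator/guanine system).
#' @param n_frames,n_states_per_frame ensemble dimensions (defaults 400
#'   frames x 10 states, i.e. 4000 states as in a 4-window x 100-snapshot
#'   protocol).
#' @param energy_range uniform vertical-excitation energy range in eV
#'   (default 2.5-6.5 eV, the near-UV/visible window of such systems).
#' @param seed integer RNG seed; the ensemble is deterministic given the
#'   seed.
#' @param mixing_noise archetype blending noise passed to [sample_omega()].
#' @param ct_direction_prob probability that a charge-transfer state (or the
#'   CT component of an excimer) transfers the electron from fragment 2 to
#'   fragment 1 (default 0.9: mostly guanine -> intercalator).
#' @param osc_meanlog,osc_sdlog log-normal parameters of the bright-class
#'   oscillator strengths.
#' @param ct_osc_scale multiplicative suppression of charge-transfer
#'   oscillator strengths (default 0.01).
#' @param guarantee_label see [sample_omega()].
#' @param model optional model label stored in a `model` column.
#' @return list with `records` (state-record data.frame as read by
#'   [read_state_table()]) and `truth` (data.frame `frame`, `state`,
#'   `class`, `ct_direction`).
#' @export
make_ensemble <- function(class_fractions = c(0.42, 0.03, 0.25, 0.30),
                          n_frames = 400, n_states_per_frame = 10,
                          energy_range = c(2.5, 6.5), seed,
                          mixing_noise = 0.05, ct_direction_prob = 0.9,
                          osc_meanlog = log(0.1), osc_sdlog = 0.6,
                          ct_osc_scale = 0.01, guarantee_label = TRUE,
                          model = NULL) {
  stopifnot(length(class_fractions) == 4, all(class_fractions >= 0),
            n_frames >= 1, n_states_per_frame >= 1,
            ct_direction_prob >= 0, ct_direction_prob <= 1)
  if (abs(sum(class_fractions) - 1) > 1e-8)
    stop("class_fractions must sum to 1", call. = FALSE)
  n <- n_frames * n_states_per_frame
  withr::with_seed(seed, {
    cls <- sample(state_classes(), n, replace = TRUE,
                  prob = class_fractions)
    dir <- ifelse(runif(n) < ct_direction_prob, "2to1", "1to2")
    energy <- runif(n, energy_range[1], energy_range[2])
    osc <- rlnorm(n, osc_meanlog, osc_sdlog)
    osc[cls == "charge_transfer"] <- osc[cls == "charge_transfer"] *
      ct_osc_scale
    oms <- matrix(0, n, 4,
                  dimnames = list(NULL, .omega_cols(2)))
    for (i in seq_len(n)) {
      om <- sample_omega(cls[i], mixing_noise = mixing_noise,
                         ct_direction = dir[i],
                         guarantee_label = guarantee_label)
      oms[i, ] <- as.vector(t(om))  # row-major om_1_1 om_1_2 om_2_1 om_2_2
    }
    records <- data.frame(
      frame = rep(seq_len(n_frames) - 1L, each = n_states_per_frame),
      state = rep(seq_len(n_states_per_frame), times = n_frames),
      energy_ev = energy, osc = osc, stringsAsFactors = FALSE)
    records <- cbind(records, as.data.frame(oms))
    if (!is.null(model)) records$model <- model
    truth <- data.frame(frame = records$frame, state = records$state,
                        class = cls, ct_direction = dir,
                        stringsAsFactors = FALSE)
    list(records = records, truth = truth)
  })
}
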