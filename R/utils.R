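# small internal numeric helpers

.norm3 <- function(v) sqrt(sum(v * v))

.unit <- function(v, what = "vector") {
  n <- .norm3(v)
  if (!is.finite(n) || n < 1e-8)
    stop("degenerate geometry: zero-length ", what, call. = FALSE)
  v / n
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# project v into the plane with unit normal n
.project_plane <- function(v, n) v - sum(v * n) * n

# rotation by `deg` degrees about unit axis (Rodrigues)
.rotation_about <- function(axis, deg) {
  a <- .unit(axis, "rotation axis")
  th <- deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# standard atomic masses (u), keyed by upper-case element symbol
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  `NA` = 22.98977, MG = 24.305, K = 39.0983, FE = 55.845, ZN = 65.38
)

# best-effort element symbol from an atom label such as "C1'", "O6", "Na+"
.element_from_label <- function(label) {
  alpha <- toupper(sub("^[^A-Za-z]*([A-Za-z]+).*$", "\\1", label))
  out <- character(length(label))
  for (i in seq_along(alpha)) {
    el <- alpha[i]
    if (el %in% names(.atomic_masses)) {
      out[i] <- el
    } else if (substr(el, 1, 2) %in% names(.atomic_masses)) {
      out[i] <- substr(el, 1, 2)
    } else {
      out[i] <- substr(el, 1, 1)
    }
  }
  out
}
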