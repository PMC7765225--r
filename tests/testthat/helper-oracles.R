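# Independent brute-force oracles, kept deliberately naive (explicit loops,
# no shared code with the implementation).

oracle_descriptors <- function(raw) {
  om <- raw / sum(raw)
  N <- nrow(om)
  hole <- numeric(N)
  elec <- numeric(N)
  for (A in 1:N) for (B in 1:N) {
    hole[A] <- hole[A] + om[A, B]
    elec[B] <- elec[B] + om[A, B]
  }
  pr <- function(p) {
    s <- 0
    for (a in seq_along(p)) s <- s + p[a]^2
    1 / s
  }
  ctv <- 0
  for (A in 1:N) for (B in 1:N) if (A != B) ctv <- ctv + om[A, B]
  posv <- function(p) {
    s <- 0
    for (a in seq_along(p)) s <- s + a * p[a]
    s
  }
  list(hole = hole, elec = elec, pr_hole = pr(hole), pr_elec = pr(elec),
       dl = (pr(hole) + pr(elec)) / 2, ctn = ctv,
       pos_i = posv(hole), pos_f = posv(elec))
}

# total-least-squares plane by direct minimization over normal angles
oracle_plane_normal <- function(pts) {
  sse <- function(par) {
    n <- c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]),
           cos(par[1]))
    d <- pts %*% n
    sum((d - mean(d))^2)
  }
  fit <- stats::optim(c(0.01, 0.01), sse, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  par <- fit$par
  c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]), cos(par[1]))
}

random_rotation <- function() {
  qr_out <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_out)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

angle_between_deg <- function(a, b) {
  acos(min(1, max(-1, sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}
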