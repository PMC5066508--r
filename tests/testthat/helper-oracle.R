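# Independent superposition oracle: dense Euler-angle grid search over
# proper rotations followed by local refinement. Uses the identity
# rmsd^2 = (|Pc|^2 + |Qc|^2 - 2 tr(R A)) / n with A = t(Pc) %*% Qc, so
# the search maximizes tr(R A). Shares no code with the SVD path.

euler_rotation <- function(a, b, g) {
  Rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry  <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz2 <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
  Rz1 %*% Ry %*% Rz2
}

oracle_superpose <- function(P, Q, step_deg = 6) {
  n <- nrow(P)
  pc <- sweep(P, 2, colMeans(P))
  qc <- sweep(Q, 2, colMeans(Q))
  A <- crossprod(pc, qc)
  # objective tr(R A) = sum over ij of R_ij A_ji = sum(R * t(A))
  tr_RA <- function(ang) {
    R <- euler_rotation(ang[1], ang[2], ang[3])
    sum(R * t(A))
  }
  step <- step_deg * pi / 180
  grid_a <- seq(0, 2 * pi - step, by = step)
  grid_b <- seq(0, pi, by = step)
  grid_g <- seq(0, 2 * pi - step, by = step)
  best <- c(0, 0, 0); best_val <- -Inf
  for (a in grid_a) for (b in grid_b) for (g in grid_g) {
    v <- tr_RA(c(a, b, g))
    if (v > best_val) { best_val <- v; best <- c(a, b, g) }
  }
  ref <- stats::optim(best, function(ang) -tr_RA(ang),
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  val <- -ref$value
  rmsd2 <- (sum(pc^2) + sum(qc^2) - 2 * val) / n
  sqrt(max(rmsd2, 0))
}
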