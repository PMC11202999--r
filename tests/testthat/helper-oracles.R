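# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: the mass-action solver is a bisection, the superposition
# oracle is a direct numeric minimization over rigid transforms.

# Solve ka (P - C)(Q - C) = C for the complex concentration by bisection.
bisect_complex_conc <- function(ka, p, q, iterations = 200) {
  g <- function(cc) ka * (p - cc) * (q - cc) - cc
  lo <- 0
  hi <- min(p, q)
  for (i in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Minimum weighted RMSD over all rigid transforms, found by direct numeric
# minimization (multi-start Nelder-Mead over axis-angle rotation +
# translation), independent of the Kabsch SVD solution.
rigid_rmsd_oracle <- function(mobile, ref, weights) {
  rot_matrix <- function(v) {
    theta <- sqrt(sum(v^2))
    if (theta < 1e-12) return(diag(3))
    k <- v / theta
    kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
                 3, 3, byrow = TRUE)
    diag(3) + sin(theta) * kx + (1 - cos(theta)) * kx %*% kx
  }
  obj <- function(par) {
    moved <- sweep(mobile %*% t(rot_matrix(par[1:3])), 2, par[4:6], `+`)
    sqrt(sum(weights * rowSums((moved - ref)^2)) / sum(weights))
  }
  starts <- rbind(rep(0, 6),
                  c(pi / 2, 0, 0, 0, 0, 0), c(0, pi / 2, 0, 0, 0, 0),
                  c(0, 0, pi / 2, 0, 0, 0), c(pi, pi / 2, 0, 0, 0, 0),
                  c(2, 2, 2, 0.1, -0.1, 0.1))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    fit <- stats::optim(fit$par, obj, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# A rigid rotation (about an arbitrary axis) plus translation, for
# invariance checks.
apply_rigid_transform <- function(coords, angle = 0.7,
                                  axis = c(1, 2, 3) / sqrt(14),
                                  shift = c(0.5, -0.3, 1.1)) {
  k <- axis / sqrt(sum(axis^2))
  kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
               3, 3, byrow = TRUE)
  rot <- diag(3) + sin(angle) * kx + (1 - cos(angle)) * kx %*% kx
  sweep(coords %*% t(rot), 2, shift, `+`)
}

# Shared fixture: the three printed binding constants by temperature (K).
ka_by_temp_fixture <- c("298.15" = 1.75e4, "304.15" = 1.62e4,
                        "310.15" = 1.27e4)
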