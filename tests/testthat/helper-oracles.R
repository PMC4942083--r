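# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# Total heat by bisection on the binding polynomial K = B/((nMt-B)(Xt-B)).
bisectTotalHeat <- function(n, K, dH, Mt, Xt, V0) {
  if (Xt == 0) return(0)
  f <- function(B) K * (n * Mt - B) * (Xt - B) - B
  lo <- 0; hi <- min(n * Mt, Xt)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  ((lo + hi) / 2) * dH * V0
}

# Monte Carlo Shrake-Rupley with random (not spiral) sphere points.
mcSasa <- function(xyz, radii, probe, nPoints = 20000, seed = 42) {
  set.seed(seed)
  r <- radii + probe
  n <- nrow(xyz)
  u <- matrix(rnorm(3 * nPoints), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  vapply(seq_len(n), function(i) {
    p <- sweep(u * r[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, nPoints)
    for (j in seq_len(n)[-i]) {
      d2 <- rowSums(sweep(p, 2, xyz[j, ])^2)
      acc <- acc & d2 > r[j]^2
    }
    4 * pi * r[i]^2 * mean(acc)
  }, numeric(1))
}

# Rigid-superposition RMSD by Euler-angle grid search plus local refinement.
gridSuperposeRmsd <- function(mobile, target, gridStep = 30) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(target, 2, colMeans(target))
  eulerR <- function(a) {
    ca <- cos(a); sa <- sin(a)
    Rz1 <- matrix(c(ca[1], sa[1], 0, -sa[1], ca[1], 0, 0, 0, 1), 3)
    Ry  <- matrix(c(ca[2], 0, -sa[2], 0, 1, 0, sa[2], 0, ca[2]), 3)
    Rz2 <- matrix(c(ca[3], sa[3], 0, -sa[3], ca[3], 0, 0, 0, 1), 3)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(a) sqrt(mean(rowSums((P %*% eulerR(a) - Q)^2)))
  step <- gridStep * pi / 180
  best <- NULL; bestVal <- Inf
  for (a1 in seq(0, 2 * pi - step, by = step))
    for (a2 in seq(0, pi, by = step))
      for (a3 in seq(0, 2 * pi - step, by = step)) {
        v <- obj(c(a1, a2, a3))
        if (v < bestVal) { bestVal <- v; best <- c(a1, a2, a3) }
      }
  opt <- optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt <- optim(opt$par, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# Torsion via normal-vector angle plus orientation sign (acos/sign route,
# distinct from the package's atan2 projection route).
oracleTorsion <- function(p1, p2, p3, p4) {
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  s <- sign(sum(cross(n1, n2) * b2))
  if (s < 0) ang <- -ang
  if (ang <= -180) ang <- ang + 360
  ang
}

# smallest absolute angular difference in degrees (handles the +/-180 seam)
angDiff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Table 2 and Table 3 association constants (1/M) and enthalpies (kcal/mol)
# as printed, used by thermodynamic-reproduction tests and fixtures.
table2K <- c(`Hairless` = 5.7e8, `H-L235A` = 1.7e7, `H-F237A` = 4.3e6,
             `H-L245A` = 1.1e8, `H-L247A` = 5.1e7, `H-W258A` = 4.3e7)
table2dH <- c(`Hairless` = -11.9, `H-L235A` = -9.6, `H-F237A` = -4.4,
              `H-L245A` = -9.3, `H-L247A` = -11.1, `H-W258A` = -8.5)
table3K <- c(`Hairless` = 5.7e8, `SuH-L445A` = 6.7e7, `SuH-L514A` = 1.8e8,
             `SuH-L445A-L514A` = 1.0e7, `SuH-L445A-F516A` = 1.8e7)
table3dH <- c(`Hairless` = -11.9, `SuH-L445A` = -12.8, `SuH-L514A` = -10.6,
              `SuH-L445A-L514A` = -7.7, `SuH-L445A-F516A` = -7.9)
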