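test_that("identical frames fluctuate nowhere", {
  ref <- caCoords(makeToyChain(8))
  arr <- array(NA_real_, c(4, nrow(ref), 3))
  for (f in 1:4) arr[f, , ] <- ref
  ens <- Ensemble(arr, labels = rownames(ref))
  expect_equal(unname(rmsf(ens, superpose = FALSE)), rep(0, 8))
  expect_equal(unname(rmsf(ens, superpose = TRUE)), rep(0, 8),
               tolerance = 1e-9)
  expect_error(rmsf(Ensemble(arr[1, , , drop = FALSE])), "2 frames")
})

test_that("isotropic Gaussian jitter gives RMSF = sigma * sqrt(3)", {
  sigma <- 0.25
  ref <- caCoords(makeToyChain(30))
  ts <- makeTwoStateEnsemble(ref, ref, nA = 10000, nB = 10000,
                             sigma = sigma, seed = 101)
  got <- rmsf(ts$ensemble, superpose = FALSE)
  expect_true(all(abs(got - sigma * sqrt(3)) / (sigma * sqrt(3)) < 0.02))
})

test_that("a two-state ensemble fluctuates most at the differing atoms", {
  ref <- caCoords(makeToyChain(20))
  refB <- ref; refB[7, ] <- refB[7, ] + c(0, 4, 0)
  ts <- makeTwoStateEnsemble(ref, refB, 200, 200, sigma = 0.2, seed = 3)
  fl <- rmsf(ts$ensemble, superpose = FALSE)
  expect_equal(which.max(fl), 7L, ignore_attr = TRUE)
})

test_that("a rigidly moving ensemble has (numerically) zero covariance after superposition", {
  ref <- caCoords(makeToyChain(12))
  arr <- array(NA_real_, c(6, nrow(ref), 3))
  for (f in 1:6) {
    R <- randomRotation(f)
    arr[f, , ] <- sweep(ref %*% R, 2, rnorm(3, sd = 5), "+")
  }
  ens <- Ensemble(arr, labels = rownames(ref))
  pca <- ensemblePca(ens, superpose = TRUE)
  expect_true(all(pca@eigenvalues <= 1e-12))
})

test_that("eigenvalue sum equals total variance and eigenvectors are orthonormal", {
  ref <- caCoords(makeToyChain(15))
  refB <- ref + matrix(rnorm(45, sd = 1), nrow(ref), 3)
  ts <- makeTwoStateEnsemble(ref, refB, 150, 150, sigma = 0.3, seed = 7)
  for (sup in c(FALSE, TRUE)) {
    pca <- ensemblePca(ts$ensemble, superpose = sup)
    fl <- rmsf(ts$ensemble, superpose = sup)
    expect_equal(sum(pca@eigenvalues), sum(fl^2), tolerance = 1e-6)
    V <- pca@eigenvectors
    expect_equal(crossprod(V), diag(ncol(V)), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_true(all(diff(pca@eigenvalues) <= 1e-12))
  }
})

test_that("PC1 of a two-cluster ensemble lies along the constructed displacement", {
  ref <- caCoords(makeToyChain(20))
  refB <- ref
  refB[10, ] <- refB[10, ] + c(0, 0, 5)
  refB[11, ] <- refB[11, ] + c(0, 3, 0)
  ts <- makeTwoStateEnsemble(ref, refB, 150, 150, sigma = 0.25, seed = 19)
  pca <- ensemblePca(ts$ensemble, superpose = FALSE)
  cosine <- abs(sum(pca@eigenvectors[, 1] * ts$truth$direction))
  expect_gt(cosine, 0.99)
  # PC1 projections separate the clusters cleanly
  pa <- pca@projections[ts$ensemble@states == "A", 1]
  pb <- pca@projections[ts$ensemble@states == "B", 1]
  expect_true(max(pa) < min(pb) || max(pb) < min(pa))
})

test_that("RMSF and eigenvalues are invariant to a global rotation of all frames", {
  ref <- caCoords(makeToyChain(10))
  ts <- makeTwoStateEnsemble(ref, ref + 0.8, 40, 40, sigma = 0.3, seed = 5)
  base <- ensemblePca(ts$ensemble, superpose = TRUE)
  fl0 <- rmsf(ts$ensemble, superpose = TRUE)
  R <- randomRotation(99)
  arr <- ts$ensemble@coords
  for (f in seq_len(dim(arr)[1])) arr[f, , ] <- arr[f, , ] %*% R
  rot <- Ensemble(arr, labels = ts$ensemble@labels)
  expect_equal(unname(rmsf(rot, superpose = TRUE)), unname(fl0),
               tolerance = 1e-6)
  expect_equal(ensemblePca(rot, superpose = TRUE)@eigenvalues,
               base@eigenvalues, tolerance = 1e-6)
})

test_that("state separation scores match their closed forms and controls", {
  ref <- caCoords(makeToyChain(10))
  # identical distributions: score stays near zero
  same <- makeTwoStateEnsemble(ref, ref, 500, 500, sigma = 0.3, seed = 23)
  pcaS <- ensemblePca(same$ensemble, superpose = FALSE)
  expect_lt(stateSeparation(pcaS@projections, same$ensemble@states)$component1,
            0.2)

  # displacement of 10 sigma along one coordinate: score ~ 10
  refB <- ref; refB[4, 1] <- refB[4, 1] + 3
  far <- makeTwoStateEnsemble(ref, refB, 500, 500, sigma = 0.3, seed = 29)
  pcaF <- ensemblePca(far$ensemble, superpose = FALSE)
  sep <- stateSeparation(pcaF@projections, far$ensemble@states)
  expect_equal(sep$component1, far$truth$expectedSeparation, tolerance = 0.1)
  expect_true(sep$distinct)

  # permuting the labels collapses the separation
  set.seed(31)
  perm <- sample(far$ensemble@states)
  expect_lt(stateSeparation(pcaF@projections, perm)$component1, 0.5)

  expect_error(stateSeparation(pcaF@projections, rep("A", 1000)),
               "two state groups")
})

test_that("ensembles convert from multi-model structures with stable labels", {
  base <- makeToyChain(4)
  xyz <- atomCoords(base)
  multi <- structureModel(atomData(base), list(xyz, xyz + 0.5, xyz + 1))
  ens <- asEnsemble(multi, atomNames = "CA")
  expect_equal(dim(ens@coords), c(3, 4, 3))
  expect_equal(ens@labels, paste0("A:", 1:4))
})
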