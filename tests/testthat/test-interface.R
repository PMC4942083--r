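twoClusters <- function(gap = 3.0) {
  # two 5-sphere clusters along x; one inter-group near contact at the seam
  set.seed(21)
  a <- matrix(rnorm(15, sd = 1.2), 5, 3)
  b <- matrix(rnorm(15, sd = 1.2), 5, 3)
  b[, 1] <- b[, 1] + max(a[, 1]) - min(b[, 1]) + gap
  makeSphereCluster(rbind(a, b), 1.7)
}

test_that("distant groups bury nothing and BSA is symmetric in its groups", {
  far <- makeSphereCluster(rbind(matrix(rnorm(9), 3, 3),
                                 matrix(rnorm(9), 3, 3) + 100), 1.7)
  repAB <- buriedSurfaceArea(far$model, 1:3, 4:6, radii = far$radii)
  expect_equal(repAB@bsaTotal, 0, tolerance = 1e-9)

  cl <- twoClusters()
  r1 <- buriedSurfaceArea(cl$model, 1:5, 6:10, radii = cl$radii)
  r2 <- buriedSurfaceArea(cl$model, 6:10, 1:5, radii = cl$radii)
  expect_gt(r1@bsaTotal, 0)
  expect_equal(r1@bsaTotal, r2@bsaTotal, tolerance = 1e-9)
})

test_that("overlapping or empty groups are input errors", {
  cl <- twoClusters()
  expect_error(buriedSurfaceArea(cl$model, 1:5, 5:10, radii = cl$radii),
               "overlap")
  expect_error(buriedSurfaceArea(cl$model, 1:5, 1:5, radii = cl$radii),
               "overlap")
  expect_error(contactResidues(cl$model, list(chains = "Z"), 6:10), "empty")
})

test_that("report totals equal brute-force atom-by-atom delta-SASA", {
  cl <- twoClusters()
  rep_ <- buriedSurfaceArea(cl$model, 1:5, 6:10, radii = cl$radii)

  # oracle: per-atom areas from three independent SASA calls
  aAlone  <- computeSasa(subsetStructure(cl$model, 1:5), cl$radii)@atomArea
  bAlone  <- computeSasa(subsetStructure(cl$model, 6:10), cl$radii)@atomArea
  together <- computeSasa(cl$model, cl$radii)@atomArea
  bruteTotal <- sum(aAlone) + sum(bAlone) - sum(together)
  expect_equal(rep_@bsaTotal, bruteTotal, tolerance = 1e-9)

  # per-residue deltas are nonnegative and sum exactly to the total
  expect_true(all(rep_@perResidue$dsasa >= 0))
  expect_equal(sum(rep_@perResidue$dsasa), rep_@bsaTotal,
               tolerance = 1e-6)
})

test_that("contact detection honours the cutoff boundary exactly", {
  mk <- function(d) makeSphereCluster(rbind(c(0, 0, 0), c(d, 0, 0)), 1.7)
  near <- mk(4.4); farther <- mk(4.6)
  expect_equal(nrow(contactResidues(near$model, 1, 2, cutoff = 4.5)), 1)
  expect_equal(nrow(contactResidues(farther$model, 1, 2, cutoff = 4.5)), 0)
  hit <- contactResidues(near$model, 1, 2, cutoff = 4.5)
  expect_equal(hit$minDistance, 4.4, tolerance = 1e-9)
})

test_that("contact pairs match a brute-force all-pairs scan on a 50-atom toy", {
  set.seed(33)
  xyz <- matrix(rnorm(150, sd = 6), 50, 3)
  cl <- makeSphereCluster(xyz, 1.7)
  idxA <- 1:25; idxB <- 26:50
  got <- contactResidues(cl$model, idxA, idxB, cutoff = 4.5)

  ref <- list()
  for (i in idxA) for (j in idxB) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d <= 4.5) {
      key <- paste0("A:", i, "|A:", j)
      ref[[key]] <- min(ref[[key]] %||% Inf, d)
    }
  }
  expect_equal(nrow(got), length(ref))
  gotKey <- paste0(got$residueA, "|", got$residueB)
  expect_setequal(gotKey, names(ref))
  expect_equal(got$minDistance, unlist(ref)[gotKey], tolerance = 1e-9,
               ignore_attr = TRUE)
  # sorted by group-A residue number
  expect_true(!is.unsorted(as.integer(sub("^A:", "", got$residueA))))
})

test_that("apo burial filter keeps strictly sub-threshold side chains and maps numbering", {
  fakeSasa <- new("SasaResult",
    atomArea = c(5, 25, 19.9), atomIndex = 1:3,
    residueArea = data.frame(chain = "A", resseq = 1:3,
                             icode = "", resname = "LEU",
                             area = c(10, 30, 25),
                             sideChainArea = c(5, 25, 19.9),
                             stringsAsFactors = FALSE),
    probe = 1.4, nPoints = 960L)

  expect_equal(as.character(apoBurialFilter(fakeSasa, c("A:1", "A:2", "A:3"))),
               c("A:1", "A:3"))
  expect_length(apoBurialFilter(fakeSasa, c("A:1", "A:2"), threshold = 0), 0)

  # fly -> mouse style renumbering through a two-column mapping
  map <- data.frame(from = c(445, 514, 516), to = c(1, 2, 3))
  hit <- apoBurialFilter(fakeSasa, c("B:445", "B:514"), mapping = map,
                         apoChain = "A")
  expect_equal(as.character(hit), "B:445")
  expect_error(apoBurialFilter(fakeSasa, "B:999", mapping = map,
                               apoChain = "A"), "unmappable")
  expect_error(apoBurialFilter(fakeSasa, "A:7"), "not resolvable")
})
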