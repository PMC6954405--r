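test_that("superposition is exact for rigidly related point sets", {
  set.seed(3)
  a <- matrix(rnorm(30), 10, 3)
  same <- superpose(a, a)
  expect_equal(same$rmsd, 0, tolerance = 1e-10)
  expect_equal(same$rotation, diag(3), tolerance = 1e-8)
  expect_equal(same$translation, c(0, 0, 0), tolerance = 1e-8)

  Rz <- CGPepDock:::.rotationMatrix(c(0, 0, 1), pi / 2)
  fit <- superpose(a %*% t(Rz) + rep(c(3, -1, 2), each = 10), a)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  expect_error(superpose(a[1:2, ], a[1:2, ]), "at least 3")
})

test_that("superposition beats 10000 random rigid transforms", {
  set.seed(4)
  a <- matrix(rnorm(30), 10, 3)
  b <- matrix(rnorm(30), 10, 3)
  best <- superpose(a, b)$rmsd
  worstCase <- min(vapply(seq_len(10000), function(i) {
    R <- CGPepDock:::.randomRotation()
    t0 <- rnorm(3, 0, 2)
    sqrt(mean(rowSums((a %*% R + rep(t0, each = 10) - b)^2)))
  }, numeric(1)))
  expect_lte(best, worstCase + 1e-12)
  # and agrees with an independent implementation
  expect_equal(best,
               bio3d::rmsd(as.vector(t(b)), as.vector(t(a)), fit = TRUE),
               tolerance = 1e-3)
})

test_that("peptide-RMSD reproduces closed-form displacements", {
  toy <- smallToy(seed = 1)
  ref <- toy$bound
  expect_equal(peptideRMSD(ref, ref), 0, tolerance = 1e-10)

  # pure peptide translation with identical receptor: RMSD = |shift|
  pepIdx <- which(ref@chain == "PEP")
  m <- ref
  m@ca[pepIdx, ] <- m@ca[pepIdx, ] + rep(c(0, 0, 2), each = 5)
  expect_equal(peptideRMSD(m, ref), 2.0, tolerance = 1e-8)

  # known per-atom displacements under an identical receptor frame
  set.seed(6)
  disp <- matrix(rnorm(15, 0, 1), 5, 3)
  m2 <- ref
  m2@ca[pepIdx, ] <- m2@ca[pepIdx, ] + disp
  expect_equal(peptideRMSD(m2, ref), sqrt(mean(rowSums(disp^2))),
               tolerance = 1e-8)

  # invariant under a rigid transform of the whole model complex
  R <- CGPepDock:::.rotationMatrix(c(2, -1, 1), 0.8)
  moved <- m2
  for (w in c("ca", "sc")) {
    mm <- slot(moved, w)
    slot(moved, w) <- mm %*% t(R) + rep(c(4, 4, -7), each = nrow(mm))
  }
  expect_equal(peptideRMSD(moved, ref), peptideRMSD(m2, ref),
               tolerance = 1e-6)

  # mismatched receptors are rejected with the offending residues named
  bad <- ref[-1]
  expect_error(peptideRMSD(bad, ref), "unmatched.*A 1")
})

test_that("interface selection matches a brute-force distance scan", {
  toy <- smallToy(seed = 2)
  ref <- toy$bound
  expect_equal(interfaceRMSD(ref, ref), 0, tolerance = 1e-10)

  cutoff <- 10
  sel <- CGPepDock:::.interfaceResidues(ref, cutoff)
  recIdx <- which(ref@chain != "PEP")
  pepIdx <- which(ref@chain == "PEP")
  expected <- integer(0)
  for (i in recIdx) {
    pts <- rbind(ref@ca[i, ], ref@cb[i, ], ref@sc[i, ], ref@cp[i, ])
    pts <- pts[!is.na(pts[, 1]), , drop = FALSE]
    hit <- FALSE
    for (j in pepIdx) {
      qts <- rbind(ref@ca[j, ], ref@cb[j, ], ref@sc[j, ], ref@cp[j, ])
      qts <- qts[!is.na(qts[, 1]), , drop = FALSE]
      if (min(CGPepDock:::.crossDist2(pts, qts)) <= cutoff^2) hit <- TRUE
    }
    if (hit) expected <- c(expected, i)
  }
  expect_identical(sel, expected)
  expect_gt(length(sel), 0)

  # peptide far away in the reference: interface undefined
  far <- ref
  far@ca[pepIdx, ] <- far@ca[pepIdx, ] + 500
  far@sc[pepIdx, ] <- far@sc[pepIdx, ] + 500
  far@cb[pepIdx, ] <- far@cb[pepIdx, ] + 500
  far@cp[pepIdx, ] <- far@cp[pepIdx, ] + 500
  expect_warning(v <- interfaceRMSD(ref, far), "empty interface")
  expect_true(is.na(v))
})

test_that("quality categories use the 3 / 5.5 and 1 / 2 A boundaries", {
  # worked-example values: restrained top-10 vs unrestrained top-10
  q <- classifyQuality(c(2.41, 13.47))
  expect_equal(as.character(q$categoryRmsd), c("high", "low"))

  expect_equal(as.character(classifyQuality(3.0)$categoryRmsd), "medium")
  expect_equal(as.character(classifyQuality(5.5)$categoryRmsd), "medium")
  expect_equal(as.character(classifyQuality(2.999999)$categoryRmsd),
               "high")
  expect_equal(as.character(classifyQuality(5.500001)$categoryRmsd),
               "low")

  qi <- classifyQuality(rep(1, 4), iRmsd = c(1.0, 1.5, 2.0, 2.1))
  expect_equal(as.character(qi$categoryIrmsd),
               c("sub_angstrom", "near_native", "near_native",
                 "not_acceptable"))

  # partition property: every non-negative value falls in exactly one
  # category, with no gaps
  grid <- c(seq(0, 20, by = 0.01), 3, 5.5)
  cat1 <- classifyQuality(grid)$categoryRmsd
  expect_false(anyNA(cat1))
  expect_identical(sort(unique(as.character(cat1))),
                   c("high", "low", "medium"))
  gridI <- seq(0, 5, by = 0.01)
  cat2 <- classifyQuality(gridI, iRmsd = gridI)$categoryIrmsd
  expect_false(anyNA(cat2))
})

test_that("benchmark summaries report best-model category fractions", {
  two <- list(list(all = c(2, 8), top = c(2, 9)),
              list(all = c(7, 6), top = c(6, 8)))
  s <- summarizeBenchmark(two)
  expect_equal(s$high, c(0.5, 0.5))
  expect_equal(s$low, c(0.5, 0.5))
  expect_equal(s$medium, c(0, 0))

  allHigh <- replicate(4, list(all = runif(5, 0, 2.9),
                               top = runif(3, 0, 2.9)),
                       simplify = FALSE)
  s2 <- summarizeBenchmark(allHigh)
  expect_equal(s2$high, c(1, 1))

  # hand enumeration on 10 synthetic cases
  set.seed(8)
  cases <- replicate(10, list(all = runif(20, 0, 12),
                              top = runif(5, 0, 12)),
                     simplify = FALSE)
  s3 <- summarizeBenchmark(cases)
  bestTop <- vapply(cases, function(cs) min(cs$top), numeric(1))
  expect_equal(s3$high[2], mean(bestTop < 3))
  expect_equal(s3$medium[2], mean(bestTop >= 3 & bestTop <= 5.5))
  expect_equal(s3$low[2], mean(bestTop > 5.5))
})

test_that("violation profiles agree with the contact filter", {
  toy <- smallToy(seed = 3)
  rs <- RestraintSet(contactRestraint(1, "C", 1, d0 = 5))
  rdist <- matrix(c(4.2, 8.0, 5.0, 6.5), 4, 1)
  traj <- bookkeepingTrajectory(toy$bound, rdist, rep(0, 4), rs)
  v <- violationProfile(traj)
  expect_equal(v[, 1], c(0, 3.0, 0, 1.5))
  kept <- filterByContact(traj)@modelIndex
  expect_identical(which(v[, 1] == 0), kept)
})
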