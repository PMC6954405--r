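test_that("interaction energy is a residue-typed square well on SC pairs", {
  pot <- contactPotential()

  # distant peptide: outside every well
  far <- pointComplex(c(0, 0, 0), rbind(c(50, 0, 0), c(53.8, 0, 0),
                                        c(57.6, 0, 0)))
  expect_identical(interactionEnergy(far, pot), 0)

  # one pair inside the well contributes exactly its table energy
  one <- pointComplex(c(0, 0, 0), rbind(c(5, 0, 0), c(20, 0, 0),
                                        c(40, 0, 0)))
  expect_equal(interactionEnergy(one, pot), pot["A", "A"])

  # brute-force double-loop oracle on a toy complex
  toy <- smallToy(seed = 3)
  cfg <- dockConfig()
  cpx <- toy$bound
  recIdx <- which(cpx@chain != "PEP")
  pepIdx <- which(cpx@chain == "PEP")
  e <- 0
  for (i in recIdx) for (j in pepIdx) {
    d <- sqrt(sum((cpx@sc[i, ] - cpx@sc[j, ])^2))
    if (d >= cfg$contactMin && d <= cfg$contactMax)
      e <- e + pot[cpx@aa[i], cpx@aa[j]]
  }
  expect_equal(interactionEnergy(cpx, pot), e)
})

test_that("excluded volume penalizes only sub-clash-radius pairs", {
  toy <- smallToy(seed = 4)
  expect_identical(excludedVolume(toy$bound), 0)

  # two CA pseudo-atoms at 3.0 A with r_clash 3.5, k = 10: 10 * 0.5^2
  cpx <- CGComplex(chain = c("A", "B", rep("PEP", 3)),
                   resno = c(1L, 1L, 1:3),
                   aa = rep("A", 5),
                   ca = rbind(c(0, 0, 0), c(3, 0, 0), c(50, 0, 0),
                              c(53.8, 0, 0), c(57.6, 0, 0)),
                   sc = rbind(c(0, 10, 0), c(3, 20, 0), c(50, 0, 2),
                              c(53.8, 0, 2), c(57.6, 0, 2)))
  expect_equal(excludedVolume(cpx), 10 * 0.5^2)

  # brute-force oracle over all non-bonded CA and SC pairs
  set.seed(9)
  n <- 12
  rnd <- CGComplex(chain = c(rep("A", 6), rep("PEP", 6)),
                   resno = c(1:6, 1:6), aa = rep("L", n),
                   ca = matrix(runif(n * 3, 0, 12), n, 3),
                   sc = matrix(runif(n * 3, 0, 12), n, 3))
  cfg <- dockConfig()
  pos <- c(1:6, 1:6)
  oracle <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sameChain <- rnd@chain[i] == rnd@chain[j]
    if (sameChain && abs(pos[i] - pos[j]) < 2) next
    dca <- sqrt(sum((rnd@ca[i, ] - rnd@ca[j, ])^2))
    dsc <- sqrt(sum((rnd@sc[i, ] - rnd@sc[j, ])^2))
    if (dca < cfg$caClash) oracle <- oracle + 10 * (cfg$caClash - dca)^2
    if (dsc < cfg$scClash) oracle <- oracle + 10 * (cfg$scClash - dsc)^2
  }
  expect_equal(excludedVolume(rnd), oracle)
})

test_that("intra-peptide terms are zero at ideal geometry, harmonic off it", {
  pep <- buildPeptide("AKLVS", seed = 2)
  expect_lt(abs(intraPeptideEnergy(pep)), 1e-6)

  # stretch the terminal bond by 1.0 A along its own direction
  stretched <- pep
  dirv <- (pep@ca[5, ] - pep@ca[4, ]) / 3.8
  stretched@ca[5, ] <- stretched@ca[5, ] + dirv
  stretched@sc[5, ] <- stretched@sc[5, ] + dirv
  e0 <- intraPeptideEnergy(pep)
  e1 <- intraPeptideEnergy(stretched)
  expect_equal(e1 - e0, 5 * 1.0^2, tolerance = 1e-6)

  # term-by-term oracle on a random conformation
  set.seed(11)
  ca <- matrix(cumsum(rnorm(18, 0, 2)), 6, 3)
  rnd <- CGComplex(chain = rep("PEP", 6), resno = 1:6,
                   aa = rep("A", 6), ca = ca, sc = ca)
  cfg <- dockConfig()
  b <- sqrt(rowSums(diff(ca)^2))
  oracle <- cfg$kBond * sum((b - 3.8)^2)
  for (i in 2:5) {
    v1 <- ca[i - 1, ] - ca[i, ]; v2 <- ca[i + 1, ] - ca[i, ]
    th <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    out <- max(0, max(75 - th, th - 150)) * pi / 180
    oracle <- oracle + cfg$kAngle * out^2
  }
  expect_equal(intraPeptideEnergy(rnd), oracle)

  # the secondary-structure bias adds a non-negative term
  expect_gte(intraPeptideEnergy(rnd, ss = "HHHHHH"),
             intraPeptideEnergy(rnd))
})

test_that("total energy decomposes additively, including restraints", {
  toy <- smallToy(seed = 5)
  cpx <- toy$bound
  e0 <- totalEnergy(cpx)
  comp <- energyComponents(e0)
  expect_equal(comp[["total"]],
               comp[["interaction"]] + comp[["intraPeptide"]] +
                 comp[["excludedVolume"]] + comp[["restraint"]])
  expect_identical(comp[["restraint"]], 0)
  expect_equal(comp[["interaction"]], interactionEnergy(cpx))
  expect_equal(comp[["excludedVolume"]], excludedVolume(cpx))

  # a restraint violated by exactly 2.3 A raises the total by 2.3
  tab <- residueTable(cpx)
  ri <- which(tab$chain != "PEP")[1]
  pi <- which(tab$chain == "PEP")[1]
  d <- sqrt(sum((cpx@sc[ri, ] - cpx@sc[pi, ])^2))
  r <- contactRestraint(tab$resno[ri], tab$chain[ri], tab$resno[pi],
                        d0 = d - 2.3, s = 1.0)
  e1 <- totalEnergy(cpx, RestraintSet(r))
  expect_equal(e1@total - e0@total, 2.3, tolerance = 1e-9)
  expect_equal(e1@restraint, 2.3, tolerance = 1e-9)
})

test_that("energies are invariant under rigid motion of the whole complex", {
  toy <- smallToy(seed = 6)
  cpx <- toy$bound
  rs <- RestraintSet(pickNativeContact(nativeContacts(cpx), seed = 1))
  R <- CGPepDock:::.rotationMatrix(c(1, 2, 3), 1.1)
  t0 <- c(5, -8, 13)
  moved <- cpx
  for (w in c("ca", "cb", "sc", "cp")) {
    m <- slot(cpx, w)
    ok <- !is.na(m[, 1])
    m[ok, ] <- m[ok, , drop = FALSE] %*% t(R) +
      rep(t0, each = sum(ok))
    slot(moved, w) <- m
  }
  a <- energyComponents(totalEnergy(cpx, rs))
  b <- energyComponents(totalEnergy(moved, rs))
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("the shipped contact potential is a valid symmetric table", {
  pot <- contactPotential()
  expect_equal(dim(pot), c(20L, 20L))
  expect_equal(pot, t(pot))
  expect_true(all(pot < 0))  # uniformly (weakly) attractive scale
  expect_error(interactionEnergy(pointComplex(c(0, 0, 0),
                                              rbind(c(5, 0, 0),
                                                    c(9, 0, 0),
                                                    c(13, 0, 0))),
                                 pot[-1, -1]),
               "no potential entry")
})
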