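test_that("contact filtering keeps models within the cutoff (inclusive)", {
  toy <- smallToy(seed = 1)
  rs <- RestraintSet(contactRestraint(1, "C", 1, d0 = 5.0))
  traj <- bookkeepingTrajectory(toy$bound,
                                rdist = matrix(c(4.9, 5.0, 5.1, 7.0,
                                                 2.0), 5, 1),
                                inter = rep(0, 5), restraints = rs)
  kept <- filterByContact(traj)
  expect_equal(kept@modelIndex, c(1L, 2L, 5L))

  # empty restraint set: identity
  emptyR <- bookkeepingTrajectory(toy$bound, matrix(0, 5, 0),
                                  rep(0, 5), RestraintSet())
  expect_equal(nModels(filterByContact(emptyR)), 5L)

  # idempotence
  expect_identical(filterByContact(kept)@modelIndex, kept@modelIndex)
})

test_that("all/any modes follow the satisfaction truth table", {
  toy <- smallToy(seed = 1)
  rs <- RestraintSet(contactRestraint(1, "C", 1, d0 = 5),
                     contactRestraint(2, "C", 2, d0 = 5))
  # satisfaction pattern over two restraints: TT, TF, FT, FF
  rd <- rbind(c(4, 4), c(4, 9), c(9, 4), c(9, 9))
  traj <- bookkeepingTrajectory(toy$bound, rd, rep(0, 4), rs)
  expect_equal(nModels(filterByContact(traj, mode = "all")), 1L)
  expect_equal(nModels(filterByContact(traj, mode = "any")), 3L)
  expect_equal(nModels(filterByContact(traj, mode = "off")), 4L)
  expect_warning(
    out <- filterByContact(traj[4], mode = "all"),
    "no model satisfies")
  expect_equal(nModels(out), 0L)
})

test_that("energy filtering keeps the lowest-interaction models", {
  toy <- smallToy(seed = 2)
  traj <- bookkeepingTrajectory(toy$bound, matrix(0, 100, 0),
                                inter = sample(1:100), RestraintSet())
  kept <- filterByEnergy(traj, nKeep = 10)
  expect_equal(sort(kept@energies$interaction), 1:10)

  # order-statistic property on random energies
  set.seed(5)
  rnd <- bookkeepingTrajectory(toy$bound, matrix(0, 50, 0),
                               inter = rnorm(50), RestraintSet())
  kept <- filterByEnergy(rnd, nKeep = 20)
  dropped <- setdiff(seq_len(50), kept@modelIndex)
  expect_lte(max(kept@energies$interaction),
             min(rnd@energies$interaction[dropped]))

  # idempotence and small-input warning
  expect_identical(filterByEnergy(kept, 20)@modelIndex, kept@modelIndex)
  expect_warning(filterByEnergy(rnd, 200), "keeping all")
})

test_that("clustering recovers well-separated pose groups exactly", {
  toy <- smallToy(seed = 3)
  ref <- toy$bound
  pepIdx <- which(ref@chain == "PEP")
  centers <- rbind(c(0, 0, 0), c(20, 0, 0), c(0, 20, 0))
  models <- list()
  truth <- integer(0)
  set.seed(7)
  for (g in 1:3) for (r in 1:6) {
    m <- ref
    shift <- centers[g, ] + rnorm(3, 0, 0.2)   # intra-group spread
    m@ca[pepIdx, ] <- m@ca[pepIdx, ] + rep(shift, each = length(pepIdx))
    m@sc[pepIdx, ] <- m@sc[pepIdx, ] + rep(shift, each = length(pepIdx))
    models <- c(models, m)
    truth <- c(truth, g)
  }
  en <- data.frame(model = 1:18, replica = 1L, sweep = 1:18,
                   interaction = 0, intraPeptide = 0,
                   excludedVolume = 0, restraint = 0, total = 0)
  traj <- CGPepDock:::.trajectoryFromModels(models, en,
                                            matrix(0, 18, 0),
                                            RestraintSet())
  rep3 <- clusterModels(traj, k = 3, seed = 1)
  expect_equal(length(unique(rep3@assignment)), 3L)
  # same partition as the construction labels
  tab <- table(truth, rep3@assignment)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("degenerate clusters score by the singleton convention", {
  toy <- smallToy(seed = 3)
  traj <- bookkeepingTrajectory(toy$bound, matrix(0, 6, 0),
                                rep(0, 6), RestraintSet())
  rep1 <- clusterModels(traj, k = 1)
  expect_equal(length(rep1@medoids), 1L)
  expect_equal(rep1@density, 6)  # identical models: density = size
})

test_that("k-medoids matches the exhaustive-search optimum on small sets", {
  set.seed(13)
  x <- matrix(rnorm(16), 8, 2)
  D <- as.matrix(dist(x))
  for (k in 2:3) {
    km <- CGPepDock:::.kmedoids(D, k, seed = 1)
    cost <- sum(apply(D[, km$medoids, drop = FALSE], 1, min))
    combos <- combn(8, k)
    best <- min(apply(combos, 2, function(m)
      sum(apply(D[, m, drop = FALSE], 1, min))))
    expect_equal(cost, best)
  }
})

test_that("the full pipeline composes filters, clustering and provenance", {
  toy <- smallToy(seed = 4)
  rs <- RestraintSet(pickNativeContact(nativeContacts(toy$bound), 3))
  traj <- syntheticTrajectory(toy$bound, nModels = 400,
                              fractionNearNative = 0.3,
                              restraints = rs, seed = 9)
  rep <- runPipeline(traj, nKeepEnergy = 100, k = 10, seed = 2)
  prov <- rep@provenance
  expect_equal(prov$input, 400L)
  expect_lte(prov$energyFilter, 100L)
  expect_equal(prov$finalModels, 10L)

  # every final model satisfies the contact criterion
  fm <- finalModels(rep)
  expect_true(all(restraintDistances(rep@trajectory)[fm, 1] <=
                    rs[[1]]@d0))

  # determinism
  rep2 <- runPipeline(traj, nKeepEnergy = 100, k = 10, seed = 2)
  expect_identical(finalModels(rep2), fm)

  # restraint filtering then energy filtering still returns
  # min(nKeep, survivors)
  survivors <- nModels(filterByContact(traj, rs))
  expect_equal(prov$contactFilter, survivors)
  expect_equal(prov$energyFilter, min(100L, survivors))
})

test_that("an impossible contact criterion triggers the loud fallback", {
  toy <- smallToy(seed = 5)
  rs <- RestraintSet(contactRestraint(1, "C", 1, d0 = 0.5))
  rdist <- matrix(runif(30, 10, 20), 30, 1)
  traj <- bookkeepingTrajectory(toy$bound, rdist, rnorm(30), rs)
  expect_warning(rep <- runPipeline(traj, nKeepEnergy = 10, k = 3),
                 "falling back")
  # fallback keeps the smallest-restraint-energy models
  expect_equal(sort(rep@trajectory@modelIndex),
               sort(order(rdist[, 1])[1:10]))
})
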