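test_that("the three equivalent input forms parse to identical restraints", {
  full <- parseRestraintLine("1060:C 6:PEP 5.0 1.0")
  noW <- parseRestraintLine("1060:C 6:PEP 5.0")
  bare <- parseRestraintLine("1060:C 6:PEP")
  for (r in list(full, noW, bare)) {
    expect_equal(r@recResno, 1060L)
    expect_equal(r@recChain, "C")
    expect_equal(r@pepResno, 6L)
    expect_equal(r@d0, 5.0)
    expect_equal(r@s, 1.0)
  }
  r2 <- parseRestraintLine("1066:C 7:PEP 5.0 1.0")
  expect_equal(r2@recResno, 1066L)
  expect_equal(r2@pepResno, 7L)
})

test_that("multi-restraint blocks accept semicolons and newlines alike", {
  semi <- parseRestraints("1060:C 6:PEP 5.0 1.0;1066:C 7:PEP 5.0 1.0")
  newl <- parseRestraints("1060:C 6:PEP 5.0 1.0\n1066:C 7:PEP 5.0 1.0")
  expect_equal(length(semi), 2L)
  expect_identical(formatRestraints(semi), formatRestraints(newl))
  expect_equal(length(parseRestraints("")), 0L)
  expect_equal(length(parseRestraints(";;\n ;")), 0L)
})

test_that("malformed restraint input is rejected with informative errors", {
  expect_error(parseRestraintLine("1060:C 6:A 5.0"), ":PEP")
  expect_error(parseRestraintLine("6:PEP 1060:C"), "receptor")
  expect_error(parseRestraintLine("1060:C 6:PEP x"), "non-numeric")
  expect_error(parseRestraintLine("1060:C 6:PEP 5.0 -1"), "negative")
  expect_error(parseRestraintLine("1060:C"), "tokens")
  expect_error(parseRestraints("1060:C 6:PEP; bogus"), "bogus")
  expect_error(parseRestraints("1:C 2:PEP;1:C 2:PEP"), "duplicate")
})

test_that("parse then serialize yields the canonical four-token form", {
  for (line in c("1060:C 6:PEP", "1060:C 6:PEP 5.0",
                 "1060:C 6:PEP 5.0 1.0"))
    expect_identical(formatRestraint(parseRestraintLine(line)),
                     "1060:C 6:PEP 5.0 1.0")
  r <- parseRestraintLine("12:A ALL:PEP 18.0 0.5")
  expect_identical(formatRestraint(r), "12:A ALL:PEP 18.0 0.5")
  expect_identical(formatRestraint(parseRestraintLine(formatRestraint(r))),
                   formatRestraint(r))
})

test_that("restraint energy follows the flat-bottom linear form exactly", {
  # boundary and slope examples
  expect_identical(restraintEnergy(5.0, d0 = 5, s = 1), 0)
  expect_equal(restraintEnergy(7.3, d0 = 5, s = 1), 2.3)
  expect_identical(restraintEnergy(4.0, d0 = 5, s = 2.5), 0)

  # exact agreement with the two-branch definition on a parameter grid
  for (d0 in c(2, 5, 8.5)) {
    for (s in c(0, 0.5, 1, 2.5)) {
      d <- seq(0, 20, by = 0.25)
      expected <- ifelse(d <= d0, 0, s * (d - d0))
      expect_equal(restraintEnergy(d, d0 = d0, s = s), expected)
    }
  }
})

test_that("restraint energy is non-negative, monotone and continuous", {
  set.seed(42)
  for (rep in seq_len(25)) {
    d0 <- runif(1, 0.5, 15)
    s <- runif(1, 0.01, 5)
    d <- sort(runif(200, 0, 30))
    e <- restraintEnergy(d, d0 = d0, s = s)
    expect_true(all(e >= 0))
    expect_true(all(diff(e) >= -1e-12))
    # zero exactly on d <= d0 (s > 0)
    expect_identical(e == 0, d <= d0)
    # continuity at the cutoff
    eps <- 1e-9
    expect_lt(restraintEnergy(d0 + eps, d0 = d0, s = s), 1e-6)
  }
})

test_that("restraint distances use SC pseudo-atoms with the minimum rule", {
  cpx <- pointComplex(c(0, 0, 0), rbind(c(3, 4, 0), c(30, 0, 0),
                                        c(0, 40, 0)))
  expect_equal(restraintDistance(cpx, contactRestraint(1, "R", 1)), 5)

  # ambiguous restraint: minimum over all peptide residues
  cpx2 <- pointComplex(c(0, 0, 0), rbind(c(9, 0, 0), c(0, 4, 0),
                                         c(0, 0, 7)))
  amb <- contactRestraint(1, "R", NA)
  expect_equal(restraintDistance(cpx2, amb), 4)

  expect_error(restraintDistance(cpx, contactRestraint(99, "R", 1)),
               "residue 99")

  # brute-force oracle on a toy complex
  toy <- makeToyComplex(toySystemSpec(seed = 5))
  tab <- residueTable(toy$bound)
  set.seed(1)
  for (k in seq_len(5)) {
    ri <- sample(which(tab$chain != "PEP"), 1)
    pi <- sample(which(tab$chain == "PEP"), 1)
    r <- contactRestraint(tab$resno[ri], tab$chain[ri], tab$resno[pi])
    expect_equal(restraintDistance(toy$bound, r),
                 sqrt(sum((toy$bound@sc[ri, ] - toy$bound@sc[pi, ])^2)))
  }
})

test_that("total restraint energy is additive over the set", {
  toy <- makeToyComplex(toySystemSpec(seed = 6))
  expect_identical(totalRestraintEnergy(toy$bound, RestraintSet()), 0)

  tab <- residueTable(toy$bound)
  set.seed(2)
  recIdx <- sample(which(tab$chain != "PEP"), 5)
  pepIdx <- sample(which(tab$chain == "PEP"), 5, replace = TRUE)
  rl <- lapply(seq_len(5), function(i)
    contactRestraint(tab$resno[recIdx[i]], tab$chain[recIdx[i]],
                     tab$resno[pepIdx[i]], d0 = runif(1, 2, 8),
                     s = runif(1, 0.2, 3)))
  # drop accidental duplicated pairs
  key <- vapply(rl, function(r) paste(r@recResno, r@recChain, r@pepResno),
                character(1))
  rl <- rl[!duplicated(key)]
  rs <- RestraintSet(rl)
  single <- vapply(rl, function(r)
    restraintEnergy(restraintDistance(toy$bound, r), r), numeric(1))
  expect_equal(totalRestraintEnergy(toy$bound, rs), sum(single))
})

test_that("ambiguous restraints use cutoff = peptide length + 12", {
  a6 <- ambiguousRestraints(10, "A", peptideLength = 6)
  expect_equal(length(a6), 1L)
  expect_equal(a6[[1]]@d0, 18.0)
  expect_true(is.na(a6[[1]]@pepResno))
  expect_equal(a6[[1]]@s, 1.0)
  expect_equal(ambiguousRestraints(10, "A", 3)[[1]]@d0, 15.0)
  expect_error(ambiguousRestraints(10, "A", 2))
})

test_that("native contacts use a strict 5 A SC-SC threshold, sorted", {
  cpx <- pointComplex(c(0, 0, 0), rbind(c(4.9, 0, 0), c(5.1, 0, 0),
                                        c(0, 30, 0)))
  nc <- nativeContacts(cpx)
  expect_equal(nrow(nc), 1L)
  expect_equal(nc$pepResno, 1L)
  expect_equal(nc$distance, 4.9)

  far <- pointComplex(c(0, 0, 0), rbind(c(50, 0, 0), c(53.8, 0, 0),
                                        c(57.6, 0, 0)))
  expect_equal(nrow(nativeContacts(far)), 0L)

  toy <- makeToyComplex(toySystemSpec(seed = 8))
  nc <- nativeContacts(toy$bound)
  rownames(nc) <- NULL
  expect_equal(nc[, c("recResno", "recChain", "pepResno", "distance")],
               toy$contacts)
  expect_true(all(diff(nc$distance) >= 0))
})

test_that("random native-contact picks are uniform and seeded", {
  contacts <- data.frame(recResno = 1:10, recChain = "C",
                         pepResno = rep(1:5, 2), distance = 1:10 / 2)
  one <- contacts[3, , drop = FALSE]
  for (s in 1:5)
    expect_equal(pickNativeContact(one, seed = s)@recResno, 3L)

  expect_identical(formatRestraint(pickNativeContact(contacts, 7)),
                   formatRestraint(pickNativeContact(contacts, 7)))

  picks <- vapply(seq_len(10000), function(s)
    pickNativeContact(contacts, seed = s)@recResno, integer(1))
  freq <- tabulate(picks, 10) / 10000
  expect_true(all(abs(freq - 0.1) <= 0.02))

  # converted restraint carries the defaults
  r <- pickNativeContact(contacts, seed = 1)
  expect_equal(r@d0, 5.0)
  expect_equal(r@s, 1.0)
})
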