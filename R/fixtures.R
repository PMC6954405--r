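## Deterministic toy receptor-peptide systems with planted binding
## pockets and known native contacts, plus synthetic trajectories, so
## that the whole pipeline is testable without any external structure.

#' Specification of a toy docking system
#'
#' @param receptorSize total receptor residues, split over three
#'   straight chains (two walls and a floor) that form an open groove
#'   (default 60).
#' @param pocketDepth depth of the groove floor below the peptide axis,
#'   in Angstrom (default 8).
#' @param peptideLength peptide residues (default 6).
#' @param nPlantedContacts number of receptor-peptide SC-SC contacts
#'   planted at known distances below 5 Angstrom (default 3).
#' @param seed integer RNG seed (default 1).
#' @return a [ToySystemSpec-class].
#' @export
toySystemSpec <- function(receptorSize = 60L, pocketDepth = 8,
                          peptideLength = 6L, nPlantedContacts = 3L,
                          seed = 1L) {
  new("ToySystemSpec", receptorSize = as.integer(receptorSize),
      pocketDepth = as.numeric(pocketDepth),
      peptideLength = as.integer(peptideLength),
      nPlantedContacts = as.integer(nPlantedContacts),
      seed = as.integer(seed))
}

setMethod("show", "ToySystemSpec", function(object) {
  cat(sprintf(paste0("ToySystemSpec: receptor %d aa, pocket %.1f A, ",
                     "peptide %d aa, %d planted contact(s), seed %d\n"),
              object@receptorSize, object@pocketDepth,
              object@peptideLength, object@nPlantedContacts,
              object@seed))
  invisible(NULL)
})

## Straight CA strand along x, centered at x = 0.
.strand <- function(n, y, z) {
  x <- (seq_len(n) - (n + 1) / 2) * CA_BOND
  cbind(x, rep(y, n), rep(z, n))
}

#' Generate a toy receptor-peptide system with a planted pocket
#'
#' The receptor consists of three straight coarse-grained chains
#' (labels A, B, C) forming an open groove: two walls and a floor. The
#' peptide lies along the groove axis with its side chains pointing
#' towards the floor. \code{nPlantedContacts} floor residues have their
#' SC pseudo-atoms placed at known distances (4.2, 4.3, ... Angstrom)
#' from the SC of successive peptide residues; all other receptor side
#' chains point away from the groove, so that the planted pairs are
#' exactly the native contacts of the bound reference. The "unbound"
#' receptor variant jitters the receptor coordinates rigidly per
#' residue to a prescribed CA-RMSD (default 1.0 Angstrom).
#'
#' Amino-acid types are drawn per seed (glycine excluded, so every
#' residue has a distinct SC site); the generated system is fully
#' deterministic for a fixed spec.
#'
#' @param spec a [ToySystemSpec-class].
#' @param unboundRmsd CA-RMSD (Angstrom) of the jittered unbound
#'   receptor relative to the bound one.
#' @return list with elements \code{bound} (reference
#'   [CGComplex-class] with peptide), \code{apo} (receptor-only,
#'   jittered), \code{contacts} (data.frame of planted contacts in
#'   [nativeContacts()] layout).
#' @examples
#' toy <- makeToyComplex(toySystemSpec(seed = 3))
#' nrow(toy$contacts)
#' @export
makeToyComplex <- function(spec = toySystemSpec(), unboundRmsd = 1.0) {
  validObject(spec)
  nPep <- spec@peptideLength
  nCon <- spec@nPlantedContacts
  depth <- spec@pocketDepth
  sizes <- rep(spec@receptorSize %/% 3L, 3L)
  sizes[3L] <- spec@receptorSize - sum(sizes[1:2])

  .withSeed(spec@seed, {
    aaPool <- setdiff(AA1, "G")
    recAA <- sample(aaPool, spec@receptorSize, replace = TRUE)
    pepAA <- sample(aaPool, nPep, replace = TRUE)

    wallY <- depth - 1.5
    recCa <- rbind(.strand(sizes[1L], wallY, -3),
                   .strand(sizes[2L], -wallY, -3),
                   .strand(sizes[3L], 0, -depth))
    chain <- rep(c("A", "B", "C"), sizes)
    resno <- unlist(lapply(sizes, seq_len))

    ## default side chains point away from the groove
    outward <- rbind(matrix(rep(c(0, 1, 0), sizes[1L]), ncol = 3L,
                            byrow = TRUE),
                     matrix(rep(c(0, -1, 0), sizes[2L]), ncol = 3L,
                            byrow = TRUE),
                     matrix(rep(c(0, 0, -1), sizes[3L]), ncol = 3L,
                            byrow = TRUE))
    recSc <- recCa + 2.0 * outward
    recCb <- recCa + 1.5 * outward

    ## zigzag peptide along the groove axis: bonds 3.8 A, pseudo-bond
    ## angles 140 degrees (within the coil range of the chain model)
    zig <- 20 * pi / 180
    steps <- cbind(rep(CA_BOND * cos(zig), nPep - 1L),
                   rep_len(c(1, -1), nPep - 1L) * CA_BOND * sin(zig),
                   rep(0, nPep - 1L))
    pepCa <- rbind(c(0, 0, 0), apply(steps, 2L, cumsum))
    pepCa <- sweep(pepCa, 2L, colMeans(pepCa))
    pepCa[, 3L] <- 0
    pepSc <- pepCa + rep(c(0, 0, -2.0), each = nPep)
    pepCb <- pepCa + rep(c(0, 0, -1.5), each = nPep)

    ## plant contacts: floor residues reoriented towards successive
    ## peptide side chains at known, distinct distances < 5 A
    floorIdx <- which(chain == "C")
    contacts <- data.frame(recResno = integer(nCon),
                           recChain = character(nCon),
                           pepResno = integer(nCon),
                           distance = numeric(nCon),
                           stringsAsFactors = FALSE)
    ## center the planted peptide residues in the chain
    pepPick <- seq_len(nCon) + (nPep - nCon) %/% 2L
    for (j in seq_len(nCon)) {
      p <- pepPick[j]
      f <- floorIdx[which.min(abs(recCa[floorIdx, 1L] - pepCa[p, 1L]))]
      floorIdx <- setdiff(floorIdx, f)
      ## distinct distances, clear of both the 5 A contact threshold
      ## and the 4.0 A edge of the interaction square well
      dTarget <- 4.2 + 0.1 * (j - 1L)
      ## plant straight down the groove normal: keeps the planted SC
      ## at least sqrt(3.57^2 + dTarget^2) > 5 A from every other
      ## peptide side chain, so the planted pairs are exactly the
      ## native contacts
      recSc[f, ] <- pepSc[p, ] + dTarget * c(0, 0, -1)
      recCb[f, ] <- recCa[f, ] + 1.5 * .unit(recSc[f, ] - recCa[f, ])
      contacts[j, ] <- list(resno[f], chain[f], p, dTarget)
    }
    contacts <- contacts[order(contacts$distance), , drop = FALSE]
    rownames(contacts) <- NULL

    cpFor <- function(ca, ch) .recomputeCp(ca, ch, NULL)
    receptorBound <- new("CGComplex", chain = chain,
                         resno = as.integer(resno), aa = recAA,
                         ca = recCa, cb = recCb, sc = recSc,
                         cp = cpFor(recCa, chain))
    pepChain <- rep(PEPTIDE_CHAIN, nPep)
    peptideRef <- new("CGComplex", chain = pepChain,
                      resno = seq_len(nPep), aa = pepAA, ca = pepCa,
                      cb = pepCb, sc = pepSc,
                      cp = cpFor(pepCa, pepChain))
    bound <- bindPeptide(receptorBound, peptideRef)

    ## unbound receptor: small rigid perturbation (rotation +
    ## translation) of each chain, scaled to an exact CA-RMSD; rigid
    ## sub-domain motion keeps the chain geometry (bond lengths)
    ## intact to second order
    delta <- matrix(0, spec@receptorSize, 3L)
    for (ch in unique(chain)) {
      idx <- which(chain == ch)
      R <- .rotationMatrix(.randomUnitVector(),
                           stats::rnorm(1L, 0, 1.5 * pi / 180))
      cen <- colMeans(recCa[idx, , drop = FALSE])
      t0 <- stats::rnorm(3L, 0, 0.6)
      delta[idx, ] <- sweep(recCa[idx, , drop = FALSE], 2L, cen) %*%
        (t(R) - diag(3L)) + rep(t0, each = length(idx))
    }
    delta <- delta * unboundRmsd / sqrt(mean(rowSums(delta^2)))
    apoCa <- recCa + delta
    apo <- new("CGComplex", chain = chain, resno = as.integer(resno),
               aa = recAA, ca = apoCa, cb = recCb + delta,
               sc = recSc + delta, cp = cpFor(apoCa, chain))

    list(bound = bound, apo = apo, contacts = contacts)
  })
}

#' Generate a synthetic docking trajectory
#'
#' Builds a labelled mixture of near-native poses (the reference
#' peptide rigidly displaced by a small, known amount) and decoys (the
#' peptide placed randomly on a distant shell), with interaction
#' energies drawn so that near-native models are enriched at low energy
#' by a configurable margin. Per-restraint SC-SC distances are recorded
#' from the actual coordinates. Intra-peptide and excluded-volume
#' components are set to zero: this generator feeds the filtering,
#' clustering and evaluation stages without running the sampler, and is
#' labelled synthetic accordingly.
#'
#' @param reference a bound [CGComplex-class] (e.g. from
#'   [makeToyComplex()]).
#' @param nModels number of models.
#' @param fractionNearNative probability that a model is near-native.
#' @param nearRmsdRange range (Angstrom) of the rigid displacement of
#'   near-native peptides; displacements are drawn uniformly within.
#' @param decoyMargin extra shell distance range for decoy placements.
#' @param energyMargin how much lower (simulation units) the mean
#'   interaction energy of near-native models is.
#' @param energySd standard deviation of the interaction energies.
#' @param restraints a [RestraintSet-class] whose SC-SC distances are
#'   recorded with every model.
#' @param seed integer RNG seed.
#' @return a [Trajectory-class]; its energy table carries an extra
#'   column \code{nearNative} with the generation label.
#' @export
syntheticTrajectory <- function(reference, nModels = 1000L,
                                fractionNearNative = 0.1,
                                nearRmsdRange = c(0.3, 2.0),
                                decoyMargin = c(5, 15),
                                energyMargin = 5, energySd = 1,
                                restraints = RestraintSet(),
                                seed = 1L) {
  stopifnot(hasPeptide(reference))
  pepIdx <- which(reference@chain == PEPTIDE_CHAIN)
  recIdx <- which(reference@chain != PEPTIDE_CHAIN)
  n <- length(reference)
  centroid <- colMeans(reference@ca[recIdx, , drop = FALSE])
  rSurface <- sqrt(max(rowSums(sweep(reference@ca[recIdx, , drop = FALSE],
                                     2L, centroid)^2)))
  rsys <- list(restraints = lapply(restraints@restraints, function(r) {
    recI <- .residueIndex(reference, r@recResno, r@recChain)
    pepI <- if (is.na(r@pepResno)) pepIdx
            else .residueIndex(reference, r@pepResno, PEPTIDE_CHAIN)
    list(recIdx = recI, pepIdx = pepI, d0 = r@d0, s = r@s)
  }))

  .withSeed(seed, {
    m <- as.integer(nModels)
    near <- stats::runif(m) < fractionNearNative
    caA <- cbA <- scA <- cpA <- array(NA_real_, dim = c(n, 3L, m))
    inter <- numeric(m)
    rdist <- matrix(0, m, length(restraints))
    pc <- colMeans(reference@ca[pepIdx, , drop = FALSE])
    for (i in seq_len(m)) {
      x <- reference
      if (near[i]) {
        shift <- .randomUnitVector() *
          stats::runif(1L, nearRmsdRange[1L], nearRmsdRange[2L])
        move <- function(mm) {
          mm[pepIdx, ] <- mm[pepIdx, , drop = FALSE] +
            rep(shift, each = length(pepIdx))
          mm
        }
        inter[i] <- stats::rnorm(1L, -energyMargin, energySd)
      } else {
        R <- .randomRotation()
        target <- centroid + .randomUnitVector() *
          (rSurface + stats::runif(1L, decoyMargin[1L], decoyMargin[2L]))
        move <- function(mm) {
          sub <- mm[pepIdx, , drop = FALSE]
          ok <- !is.na(sub[, 1L])
          sub[ok, ] <- sweep(sweep(sub[ok, , drop = FALSE], 2L, pc) %*%
                               t(R), 2L, target, "+")
          mm[pepIdx, ] <- sub
          mm
        }
        inter[i] <- stats::rnorm(1L, 0, energySd)
      }
      caA[, , i] <- move(x@ca)
      cbA[, , i] <- move(x@cb)
      scA[, , i] <- move(x@sc)
      cpA[, , i] <- move(x@cp)
      if (length(restraints) > 0L)
        rdist[i, ] <- .restraintDistsFast(scA[, , i], rsys)
    }
    rEnergy <- if (length(restraints) > 0L) {
      d0 <- vapply(restraints@restraints, function(r) r@d0, numeric(1L))
      s <- vapply(restraints@restraints, function(r) r@s, numeric(1L))
      viol <- sweep(rdist, 2L, d0)
      viol[viol < 0] <- 0
      as.vector(viol %*% s)
    } else numeric(m)
    energies <- data.frame(model = seq_len(m), replica = 1L,
                           sweep = seq_len(m), interaction = inter,
                           intraPeptide = 0, excludedVolume = 0,
                           restraint = rEnergy,
                           total = inter + rEnergy,
                           nearNative = near)
    new("Trajectory", template = reference, ca = caA, cb = cbA,
        sc = scA, cp = cpA, energies = energies,
        restraintDistances = rdist, restraints = restraints,
        modelIndex = seq_len(m))
  })
}
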