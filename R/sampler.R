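## Replica-exchange Monte Carlo docking of a flexible peptide around a
## near-rigid, tethered receptor.
##
## Internally the sampler works on plain coordinate matrices plus a
## precomputed "system" description (pair lists, potential lookups,
## restraint indices), so that per-move energy updates touch only the
## components a move can change:
##   - peptide moves: interaction, peptide-involving excluded volume,
##     intra-peptide geometry, restraints
##   - receptor jitter: interaction, all excluded volume, restraints,
##     tether
## The receptor-receptor excluded-volume term (the dominant pair count)
## is therefore skipped for the frequent peptide moves.

.buildSystem <- function(receptorCG, peptideCG, restraints, potential,
                         ss, config) {
  combined <- bindPeptide(receptorCG, peptideCG)
  n <- length(combined)
  idxRec <- which(combined@chain != PEPTIDE_CHAIN)
  idxPep <- which(combined@chain == PEPTIDE_CHAIN)
  pairs <- .evPairs(combined@chain)
  pepInvolved <- pairs[, 1L] %in% idxPep | pairs[, 2L] %in% idxPep
  miss <- setdiff(unique(combined@aa), rownames(potential))
  if (length(miss))
    stop("no potential entry for residue type(s): ",
         paste(miss, collapse = ", "))
  rlist <- lapply(restraints@restraints, function(r) {
    recIdx <- .residueIndex(combined, r@recResno, r@recChain)
    pepIdx <- if (is.na(r@pepResno)) idxPep
              else .residueIndex(combined, r@pepResno, PEPTIDE_CHAIN)
    list(recIdx = recIdx, pepIdx = pepIdx, d0 = r@d0, s = r@s)
  })
  ssv <- if (is.null(ss)) NULL else ss
  list(combined = combined, n = n, idxRec = idxRec, idxPep = idxPep,
       nPep = length(idxPep), nRec = length(idxRec),
       pairsRR = pairs[!pepInvolved, , drop = FALSE],
       pairsPX = pairs[pepInvolved, , drop = FALSE],
       eMat = potential[combined@aa[idxRec], combined@aa[idxPep],
                        drop = FALSE],
       wellLo2 = config$contactMin^2, wellHi2 = config$contactMax^2,
       refCA = combined@ca[idxRec, , drop = FALSE],
       restraints = rlist, ss = ssv, cfg = config)
}

.stateFromComplex <- function(x)
  list(ca = x@ca, cb = x@cb, sc = x@sc)

.eInterFast <- function(sc, sys) {
  d2 <- .crossDist2(sc[sys$idxRec, , drop = FALSE],
                    sc[sys$idxPep, , drop = FALSE])
  sum(sys$eMat[d2 >= sys$wellLo2 & d2 <= sys$wellHi2])
}

.eRestrFast <- function(sc, sys) {
  e <- 0
  for (r in sys$restraints) {
    d2 <- colSums((t(sc[r$pepIdx, , drop = FALSE]) - sc[r$recIdx, ])^2)
    d <- sqrt(min(d2))
    if (d > r$d0) e <- e + r$s * (d - r$d0)
  }
  e
}

.restraintDistsFast <- function(sc, sys)
  vapply(sys$restraints, function(r)
    sqrt(min(colSums((t(sc[r$pepIdx, , drop = FALSE]) -
                        sc[r$recIdx, ])^2))), numeric(1L))

.eTetherFast <- function(ca, sys)
  sys$cfg$kTether * sum((ca[sys$idxRec, , drop = FALSE] - sys$refCA)^2)

## Full component vector for a state.
.compEnergies <- function(st, sys) {
  c(inter = .eInterFast(st$sc, sys),
    intra = .intraEnergy(st$ca[sys$idxPep, , drop = FALSE], sys$ss,
                         sys$cfg),
    evRR = .evEnergy(st$ca, st$sc, sys$pairsRR, sys$cfg),
    evPX = .evEnergy(st$ca, st$sc, sys$pairsPX, sys$cfg),
    restr = .eRestrFast(st$sc, sys),
    tether = .eTetherFast(st$ca, sys))
}

## Components a move class can change.
.PEP_COMPS <- c("inter", "intra", "evPX", "restr")
.REC_COMPS <- c("inter", "evRR", "evPX", "restr", "tether")

.partialEnergies <- function(st, sys, which) {
  out <- numeric(length(which))
  names(out) <- which
  for (w in which)
    out[[w]] <- switch(w,
      inter = .eInterFast(st$sc, sys),
      intra = .intraEnergy(st$ca[sys$idxPep, , drop = FALSE], sys$ss,
                           sys$cfg),
      evRR = .evEnergy(st$ca, st$sc, sys$pairsRR, sys$cfg),
      evPX = .evEnergy(st$ca, st$sc, sys$pairsPX, sys$cfg),
      restr = .eRestrFast(st$sc, sys),
      tether = .eTetherFast(st$ca, sys))
  out
}

## Metropolis acceptance for an energy change dE at temperature T.
.metropolisAccept <- function(dE, temperature) {
  dE <= 0 || stats::runif(1L) < exp(-dE / temperature)
}

## Replica-exchange acceptance for configurations with energies Ei, Ej
## at temperatures Ti < Tj: min(1, exp((1/Ti - 1/Tj) * (Ei - Ej))).
.exchangeAccept <- function(Ei, Ej, Ti, Tj) {
  arg <- (1 / Ti - 1 / Tj) * (Ei - Ej)
  arg >= 0 || stats::runif(1L) < exp(arg)
}

## Apply a rigid shift/rotation to selected residues of a state copy.
.shiftResidues <- function(st, idx, delta) {
  st$ca[idx, ] <- st$ca[idx, ] + rep(delta, each = length(idx))
  st$sc[idx, ] <- st$sc[idx, ] + rep(delta, each = length(idx))
  ok <- !is.na(st$cb[idx, 1L])
  if (any(ok))
    st$cb[idx[ok], ] <- st$cb[idx[ok], ] +
      rep(delta, each = sum(ok))
  st
}

.rotateResidues <- function(st, idx, center, R) {
  tR <- t(R)
  rot <- function(m) sweep(sweep(m, 2L, center) %*% tR, 2L, center, "+")
  st$ca[idx, ] <- rot(st$ca[idx, , drop = FALSE])
  st$sc[idx, ] <- rot(st$sc[idx, , drop = FALSE])
  ok <- !is.na(st$cb[idx, 1L])
  if (any(ok))
    st$cb[idx[ok], ] <- rot(st$cb[idx[ok], , drop = FALSE])
  st
}

## One Monte Carlo sweep on the internal state. Returns updated state,
## cached component energies and acceptance counts.
.mcSweepState <- function(st, comps, sys, temperature) {
  cfg <- sys$cfg
  acc <- 0L
  prop <- 0L

  tryMove <- function(newSt, affected) {
    prop <<- prop + 1L
    oldPart <- comps[affected]
    newPart <- .partialEnergies(newSt, sys, affected)
    dE <- sum(newPart) - sum(oldPart)
    if (.metropolisAccept(dE, temperature)) {
      st <<- newSt
      comps[affected] <<- newPart
      acc <<- acc + 1L
    }
  }

  ## local peptide moves (single-residue displacement or two-residue
  ## crankshaft)
  for (k in seq_len(sys$nPep)) {
    if (sys$nPep >= 4L && stats::runif(1L) < 0.3) {
      i <- 1L + sample.int(sys$nPep - 3L, 1L)
      idx <- sys$idxPep[c(i, i + 1L)]
      axisA <- st$ca[sys$idxPep[i - 1L], ]
      axisB <- st$ca[sys$idxPep[i + 2L], ]
      ax <- axisB - axisA
      if (sum(ax * ax) > 1e-8) {
        ang <- stats::runif(1L, -cfg$maxRigidRot, cfg$maxRigidRot) * pi / 180
        R <- .rotationMatrix(ax, ang)
        tryMove(.rotateResidues(st, idx, axisA, R), .PEP_COMPS)
        next
      }
    }
    i <- sys$idxPep[sample.int(sys$nPep, 1L)]
    delta <- .randomUnitVector() * stats::runif(1L, 0, cfg$maxLocalStep)
    tryMove(.shiftResidues(st, i, delta), .PEP_COMPS)
  }

  ## one rigid-body peptide move
  if (stats::runif(1L) < 0.5) {
    delta <- .randomUnitVector() * stats::runif(1L, 0, cfg$maxRigidTrans)
    tryMove(.shiftResidues(st, sys$idxPep, delta), .PEP_COMPS)
  } else {
    ang <- stats::runif(1L, -cfg$maxRigidRot, cfg$maxRigidRot) * pi / 180
    R <- .rotationMatrix(.randomUnitVector(), ang)
    center <- colMeans(st$ca[sys$idxPep, , drop = FALSE])
    tryMove(.rotateResidues(st, sys$idxPep, center, R), .PEP_COMPS)
  }

  ## receptor CA jitter, tethered to the input coordinates
  for (k in seq_len(max(1L, round(sys$nRec / 10)))) {
    i <- sys$idxRec[sample.int(sys$nRec, 1L)]
    delta <- .randomUnitVector() * stats::runif(1L, 0, cfg$maxJitter)
    tryMove(.shiftResidues(st, i, delta), .REC_COMPS)
  }

  list(state = st, comps = comps, accepted = acc, proposed = prop)
}

## Random rotation matrix approximately uniform on SO(3) (QR of a
## Gaussian matrix with sign fix).
.randomRotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  Q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  Q <- Q %*% diag(sign(d))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

.placePeptideOnce <- function(receptorCG, peptideCG, config) {
  recCa <- receptorCG@ca
  centroid <- colMeans(recCa)
  rSurface <- sqrt(max(rowSums(sweep(recCa, 2L, centroid)^2)))
  shell <- rSurface + config$margin
  dir <- .randomUnitVector()
  target <- centroid + shell * dir
  R <- .randomRotation()
  pep <- peptideCG
  pc <- colMeans(pep@ca)
  rot <- function(m) {
    ok <- !is.na(m[, 1L])
    m[ok, ] <- sweep(sweep(m[ok, , drop = FALSE], 2L, pc) %*% t(R),
                     2L, target, "+")
    m
  }
  pep@ca <- rot(pep@ca); pep@cb <- rot(pep@cb)
  pep@sc <- rot(pep@sc); pep@cp <- rot(pep@cp)
  bindPeptide(receptorCG, pep)
}

.randomPlacementInternal <- function(receptorCG, peptideCG, config,
                                     maxTries = 1000L) {
  for (k in seq_len(maxTries)) {
    cand <- .placePeptideOnce(receptorCG, peptideCG, config)
    if (excludedVolume(cand, config) == 0) return(cand)
  }
  stop("no clash-free peptide placement found in ", maxTries,
       " tries; consider a larger 'margin'")
}

#' Random initial placement of the peptide around the receptor
#'
#' Places the peptide centroid uniformly on a shell at distance
#' \code{R_surface + margin} from the receptor centroid (where
#' \code{R_surface} is the maximal CA distance from the centroid) with a
#' random orientation, rejection-sampling until the placement is free of
#' steric clashes (excluded volume exactly zero).
#'
#' @param receptor a receptor-only [CGComplex-class].
#' @param peptide a peptide [CGComplex-class] (e.g. from
#'   [buildPeptide()]).
#' @param seed integer RNG seed (\code{NULL}: use the current stream).
#' @param config configuration from [dockConfig()]; uses \code{margin}.
#' @return a clash-free [CGComplex-class] of receptor plus peptide.
#' @export
randomPlacement <- function(receptor, peptide, seed = NULL,
                            config = dockConfig()) {
  .withSeed(seed,
            .randomPlacementInternal(receptor(receptor), peptide, config))
}

#' One Monte Carlo sweep on a complex
#'
#' A sweep consists of one local move attempt per peptide residue
#' (single-residue displacement up to \code{maxLocalStep}, or a
#' two-residue crankshaft about the axis through the flanking CA atoms),
#' one rigid-body peptide move (translation up to \code{maxRigidTrans}
#' or rotation up to \code{maxRigidRot} degrees) and \code{n_rec/10}
#' single-residue receptor jitter moves (up to \code{maxJitter},
#' harmonically tethered to the input receptor coordinates with constant
#' \code{kTether}). Each proposal is accepted by the Metropolis
#' criterion on the total energy including the restraint term.
#'
#' @param complex a [CGComplex-class] with receptor and peptide.
#' @param temperature MC temperature (simulation units).
#' @param restraints a [RestraintSet-class].
#' @param potential contact table from [contactPotential()].
#' @param ss optional peptide secondary-structure string.
#' @param config configuration from [dockConfig()].
#' @param seed integer RNG seed (\code{NULL}: current stream).
#' @return list with elements \code{complex} (updated),
#'   \code{accepted}, \code{proposed}.
#' @export
mcSweep <- function(complex, temperature, restraints = RestraintSet(),
                    potential = contactPotential(), ss = NULL,
                    config = dockConfig(), seed = NULL) {
  sys <- .buildSystem(receptor(complex), peptide(complex), restraints,
                      potential, ss, config)
  st <- .stateFromComplex(complex)
  comps <- .compEnergies(st, sys)
  res <- .withSeed(seed, .mcSweepState(st, comps, sys, temperature))
  out <- complex
  out@ca <- res$state$ca
  out@cb <- res$state$cb
  out@sc <- res$state$sc
  out@cp <- .recomputeCp(res$state$ca, out@chain, out@cp)
  list(complex = out, accepted = res$accepted, proposed = res$proposed)
}

## CP pseudo-atoms as CA-CA midpoints within each chain (snapshots of
## moving models; the all-atom peptide-bond midpoint is not available
## once residues have moved).
.recomputeCp <- function(ca, chain, cpOld) {
  cp <- matrix(NA_real_, nrow(ca), 3L)
  n <- nrow(ca)
  same <- chain[-n] == chain[-1L]
  i <- which(same)
  cp[i, ] <- (ca[i, , drop = FALSE] + ca[i + 1L, , drop = FALSE]) / 2
  cp
}

#' Geometric replica temperature ladder
#'
#' @param nReplicas number of replicas (>= 2).
#' @param tMin,tMax ladder bounds.
#' @return strictly increasing numeric vector of temperatures.
#' @export
replicaLadder <- function(nReplicas = 10L, tMin = 1.0, tMax = 3.0) {
  stopifnot(nReplicas >= 2L, tMax > tMin, tMin > 0)
  tMin * (tMax / tMin)^((seq_len(nReplicas) - 1L) / (nReplicas - 1L))
}

#' Replica-exchange Monte Carlo docking
#'
#' Runs the docking simulation: the peptide is built from its sequence
#' as a random self-avoiding chain, placed randomly around the receptor
#' independently for every replica, and sampled with replica-exchange
#' Metropolis Monte Carlo at a geometric temperature ladder. The peptide
#' is fully flexible; the receptor fluctuates around its input
#' coordinates under a harmonic tether. Contact restraints, if given,
#' contribute their linear flat-bottom energy term throughout the
#' simulation. Snapshots are taken at fixed sweep intervals evenly
#' across all replicas until \code{nModels} conformations (default
#' 10000) have been collected; each snapshot records the full energy
#' decomposition and the current per-restraint SC-SC distances.
#'
#' The run is deterministic (bit-reproducible) for a fixed seed.
#'
#' @param receptor a receptor [CGComplex-class] (a peptide chain, if
#'   present, is dropped).
#' @param peptideSeq peptide sequence (one-letter) or a prebuilt peptide
#'   [CGComplex-class].
#' @param ss optional peptide secondary-structure string
#'   (\code{H}/\code{E}/\code{C}).
#' @param restraints a [RestraintSet-class] (empty: unrestrained
#'   docking).
#' @param config configuration from [dockConfig()].
#' @param potential contact table from [contactPotential()].
#' @param seed integer RNG seed.
#' @return a [Trajectory-class] with \code{nModels} models.
#' @examples
#' toy <- makeToyComplex(toySystemSpec(receptorSize = 30,
#'                                     peptideLength = 4, seed = 1))
#' cfg <- dockConfig(nModels = 20, nReplicas = 2, burnIn = 2)
#' traj <- runDocking(toy$apo, "HAGP", config = cfg, seed = 7)
#' nModels(traj)
#' @export
runDocking <- function(receptor, peptideSeq, ss = NULL,
                       restraints = RestraintSet(),
                       config = dockConfig(),
                       potential = contactPotential(), seed = 1L) {
  receptorCG <- receptor(receptor)
  .withSeed(seed, {
    pep <- if (is(peptideSeq, "CGComplex")) peptideSeq
           else {
             aa <- strsplit(toupper(peptideSeq), "")[[1L]]
             ssv <- if (is.null(ss)) rep("C", length(aa))
                    else strsplit(toupper(ss), "")[[1L]]
             .buildPeptideInternal(aa, ssv)
           }
    sys <- .buildSystem(receptorCG, pep, restraints, potential, ss,
                        config)
    temps <- replicaLadder(config$nReplicas, config$tMin, config$tMax)
    nRep <- config$nReplicas
    states <- vector("list", nRep)
    comps <- vector("list", nRep)
    for (r in seq_len(nRep)) {
      cand <- .randomPlacementInternal(receptorCG, pep, config)
      states[[r]] <- .stateFromComplex(cand)
      comps[[r]] <- .compEnergies(states[[r]], sys)
    }

    m <- as.integer(config$nModels)
    n <- sys$n
    caA <- cbA <- scA <- cpA <- array(NA_real_, dim = c(n, 3L, m))
    eTab <- matrix(0, m, 5L)
    rdist <- matrix(0, m, length(restraints))
    replicaOf <- integer(m)
    sweepOf <- integer(m)

    collected <- 0L
    sweep_ <- 0L
    exchangeParity <- 0L
    while (collected < m) {
      sweep_ <- sweep_ + 1L
      for (r in seq_len(nRep)) {
        res <- .mcSweepState(states[[r]], comps[[r]], sys, temps[r])
        states[[r]] <- res$state
        comps[[r]] <- res$comps
      }
      if (sweep_ %% config$exchangeInterval == 0L && nRep >= 2L) {
        exchangeParity <- 1L - exchangeParity
        start <- 1L + exchangeParity
        first <- if (start <= nRep - 1L)
          seq.int(start, nRep - 1L, by = 2L) else integer(0L)
        for (i in first) {
          Ei <- sum(comps[[i]])
          Ej <- sum(comps[[i + 1L]])
          if (.exchangeAccept(Ei, Ej, temps[i], temps[i + 1L])) {
            tmp <- states[[i]]; states[[i]] <- states[[i + 1L]]
            states[[i + 1L]] <- tmp
            tmp <- comps[[i]]; comps[[i]] <- comps[[i + 1L]]
            comps[[i + 1L]] <- tmp
          }
        }
      }
      if (sweep_ > config$burnIn &&
          (sweep_ - config$burnIn) %% config$snapshotInterval == 0L) {
        for (r in seq_len(nRep)) {
          if (collected >= m) break
          collected <- collected + 1L
          st <- states[[r]]
          caA[, , collected] <- st$ca
          cbA[, , collected] <- st$cb
          scA[, , collected] <- st$sc
          cpA[, , collected] <- .recomputeCp(st$ca, sys$combined@chain,
                                             NULL)
          cmp <- comps[[r]]
          ev <- cmp[["evRR"]] + cmp[["evPX"]]
          eTab[collected, ] <- c(cmp[["inter"]], cmp[["intra"]], ev,
                                 cmp[["restr"]],
                                 cmp[["inter"]] + cmp[["intra"]] + ev +
                                   cmp[["restr"]])
          if (length(restraints) > 0L)
            rdist[collected, ] <- .restraintDistsFast(st$sc, sys)
          replicaOf[collected] <- r
          sweepOf[collected] <- sweep_
        }
      }
    }

    energies <- data.frame(model = seq_len(m), replica = replicaOf,
                           sweep = sweepOf,
                           interaction = eTab[, 1L],
                           intraPeptide = eTab[, 2L],
                           excludedVolume = eTab[, 3L],
                           restraint = eTab[, 4L], total = eTab[, 5L])
    new("Trajectory", template = sys$combined, ca = caA, cb = cbA,
        sc = scA, cp = cpA, energies = energies,
        restraintDistances = rdist, restraints = restraints,
        modelIndex = seq_len(m))
  })
}
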