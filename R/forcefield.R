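## Simplified coarse-grained energy model: residue-type square-well
## receptor-peptide contacts, soft-core excluded volume, local peptide
## geometry terms, plus the contact-restraint term. A deliberately
## transparent, fully configurable potential: every constant lives in
## one config block and the 20 x 20 contact table is a plain-text file.

#' Load a residue-residue contact potential table
#'
#' Reads a symmetric 20 x 20 matrix of contact energies (simulation
#' units, negative = attractive) with one-letter amino-acid codes as
#' header row and first column. The table shipped with the package is a
#' hydrophobicity-derived scale: contacts between hydrophobic residues
#' are the most favourable, in the spirit of knowledge-based
#' residue-contact statistics.
#'
#' @param file path to a table file; default: the packaged scale.
#' @return a named 20 x 20 numeric matrix.
#' @export
contactPotential <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "contact_potential.tsv",
                        package = "CGPepDock", mustWork = TRUE)
  m <- as.matrix(utils::read.table(file, header = TRUE, row.names = 1L,
                                   check.names = FALSE))
  if (!all(AA1 %in% rownames(m)) || !all(AA1 %in% colnames(m)))
    stop("potential table must cover all 20 amino acids")
  if (max(abs(m - t(m))) > 1e-8)
    stop("potential table must be symmetric")
  m
}

#' Docking configuration
#'
#' All tunable constants of the energy model and the sampler in one
#' block. Values can be overridden by a YAML file of key/value pairs
#' and/or by named arguments (arguments win).
#'
#' Energy-model keys (energies in simulation units, distances in
#' Angstrom): \code{contactMin}/\code{contactMax} square-well bounds of
#' the receptor-peptide contact term (4.0/6.5); \code{caClash},
#' \code{scClash} soft-core radii (3.5/3.0); \code{kClash} repulsion
#' constant (10 per A^2); \code{kBond}, \code{bondLength} peptide
#' virtual-bond term (5, 3.8); \code{kAngle} flat-bottom pseudo-angle
#' term outside \[\code{angleMin}, \code{angleMax}\] = \[75, 150\]
#' degrees (5 per rad^2); \code{wSS} secondary-structure bias weight
#' (0.5); \code{kTether} receptor positional-restraint constant (1.0
#' per A^2).
#'
#' Sampler keys: \code{nModels} (10000), \code{nReplicas} (10),
#' \code{tMin}/\code{tMax} temperature-ladder bounds (1.0/3.0),
#' \code{exchangeInterval} sweeps between replica-exchange attempts
#' (10), \code{snapshotInterval} sweeps between snapshots (1),
#' \code{burnIn} discarded initial sweeps (50), move-set magnitudes
#' \code{maxLocalStep} (0.7 A), \code{maxRigidTrans} (2 A),
#' \code{maxRigidRot} (30 degrees), \code{maxJitter} (0.3 A), and the
#' placement shell \code{margin} (10 A).
#'
#' @param file optional YAML file with overrides.
#' @param ... named overrides applied after the file.
#' @return a named list of configuration values.
#' @examples
#' cfg <- dockConfig(nModels = 200, nReplicas = 2)
#' @export
dockConfig <- function(file = NULL, ...) {
  cfg <- list(
    contactMin = 4.0, contactMax = 6.5,
    caClash = 3.5, scClash = 3.0, kClash = 10,
    kBond = 5, bondLength = CA_BOND,
    angleMin = ANGLE_RANGE[1L], angleMax = ANGLE_RANGE[2L], kAngle = 5,
    wSS = 0.5, kTether = 1.0,
    nModels = 10000L, nReplicas = 10L, tMin = 1.0, tMax = 3.0,
    exchangeInterval = 10L, snapshotInterval = 1L, burnIn = 50L,
    maxLocalStep = 0.7, maxRigidTrans = 2.0, maxRigidRot = 30,
    maxJitter = 0.3, margin = 10)
  if (!is.null(file))
    cfg <- utils::modifyList(cfg, yaml::read_yaml(file))
  utils::modifyList(cfg, list(...))
}

#' Receptor-peptide interaction energy
#'
#' Sum over receptor-peptide residue pairs of a residue-type-dependent
#' square well: the pair contributes its table energy \code{e(a, b)}
#' when the SC-SC distance lies within \[\code{contactMin},
#' \code{contactMax}\] (default \[4.0, 6.5\] Angstrom) and zero
#' otherwise. This interaction energy is the filtering key of the
#' docking pipeline.
#'
#' @param complex a [CGComplex-class] with a peptide chain.
#' @param potential 20 x 20 contact table from [contactPotential()].
#' @param config configuration list from [dockConfig()].
#' @return numeric energy (simulation units).
#' @export
interactionEnergy <- function(complex, potential = contactPotential(),
                              config = dockConfig()) {
  recIdx <- which(complex@chain != PEPTIDE_CHAIN)
  pepIdx <- which(complex@chain == PEPTIDE_CHAIN)
  if (length(pepIdx) == 0L) return(0)
  miss <- setdiff(unique(complex@aa), rownames(potential))
  if (length(miss))
    stop("no potential entry for residue type(s): ",
         paste(miss, collapse = ", "))
  e <- potential[complex@aa[recIdx], complex@aa[pepIdx], drop = FALSE]
  d2 <- .crossDist2(complex@sc[recIdx, , drop = FALSE],
                    complex@sc[pepIdx, , drop = FALSE])
  inWell <- d2 >= config$contactMin^2 & d2 <= config$contactMax^2
  sum(e[inWell])
}

## Excluded-volume pair lists: all inter-chain pairs plus intra-chain
## pairs separated by at least two positions, for CA-CA and SC-SC.
.evPairs <- function(chain) {
  n <- length(chain)
  pos <- unlist(lapply(unique(chain), function(ch) seq_len(sum(chain == ch))))
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sameChain <- chain[ij[, 1L]] == chain[ij[, 2L]]
  bonded <- sameChain & abs(pos[ij[, 1L]] - pos[ij[, 2L]]) < 2L
  ij[!bonded, , drop = FALSE]
}

#' Soft-core excluded-volume energy
#'
#' Quadratic repulsion \code{kClash * (r_clash - d)^2} for every CA-CA
#' and SC-SC pseudo-atom pair closer than its clash radius; pairs of
#' directly bonded neighbours within a chain are skipped.
#'
#' @inheritParams interactionEnergy
#' @return numeric energy (zero for clash-free conformations).
#' @export
excludedVolume <- function(complex, config = dockConfig()) {
  pairs <- .evPairs(complex@chain)
  .evEnergy(complex@ca, complex@sc, pairs, config)
}

.evEnergy <- function(ca, sc, pairs, config) {
  if (nrow(pairs) == 0L) return(0)
  e <- 0
  for (set in list(list(x = ca, rc = config$caClash),
                   list(x = sc, rc = config$scClash))) {
    d <- .rowDist(set$x[pairs[, 1L], , drop = FALSE],
                  set$x[pairs[, 2L], , drop = FALSE])
    v <- d < set$rc
    if (any(v)) e <- e + config$kClash * sum((set$rc - d[v])^2)
  }
  e
}

#' Local peptide geometry energy
#'
#' Harmonic restraint of the peptide's virtual CA-CA bonds to 3.8
#' Angstrom plus a flat-bottom pseudo-bond-angle term that is zero
#' within \[75, 150\] degrees and harmonic (in radians) outside. With a
#' secondary-structure string, an additional bias of weight \code{wSS}
#' pulls pseudo-angles (and pseudo-dihedrals, where all four residues
#' share the assignment) towards helical (\code{H}) or extended
#' (\code{E}) target values; coil (\code{C}) adds nothing.
#'
#' @param peptide a [CGComplex-class] peptide chain (or a complex; only
#'   the peptide chain is used).
#' @param ss optional secondary-structure string (\code{H}/\code{E}/
#'   \code{C}), one letter per peptide residue.
#' @param config configuration list from [dockConfig()].
#' @return numeric energy.
#' @export
intraPeptideEnergy <- function(peptide, ss = NULL,
                               config = dockConfig()) {
  ca <- if (hasPeptide(peptide)) caCoords(peptide, PEPTIDE_CHAIN)
        else caCoords(peptide)
  .intraEnergy(ca, ss, config)
}

## Secondary-structure target angles (degrees).
SS_TARGETS <- list(H = c(theta = 91, phi = 52),
                   E = c(theta = 125, phi = 200))

.intraEnergy <- function(ca, ss, config) {
  n <- nrow(ca)
  if (n < 2L) return(0)
  b <- .rowDist(ca[-n, , drop = FALSE], ca[-1L, , drop = FALSE])
  e <- config$kBond * sum((b - config$bondLength)^2)
  if (n >= 3L) {
    th <- .angleDeg(ca[1:(n - 2L), , drop = FALSE],
                    ca[2:(n - 1L), , drop = FALSE],
                    ca[3:n, , drop = FALSE])
    lo <- config$angleMin; hi <- config$angleMax
    out <- pmax(0, pmax(lo - th, th - hi)) * pi / 180
    e <- e + config$kAngle * sum(out^2)
  }
  if (!is.null(ss)) {
    ssv <- strsplit(toupper(ss), "")[[1L]]
    stopifnot(length(ssv) == n)
    if (n >= 3L) {
      for (i in 2:(n - 1L)) {
        t <- SS_TARGETS[[ssv[i]]]
        if (is.null(t)) next
        dth <- (.angleDeg(ca[i - 1L, , drop = FALSE],
                          ca[i, , drop = FALSE],
                          ca[i + 1L, , drop = FALSE]) -
                  t[["theta"]]) * pi / 180
        e <- e + config$wSS * dth^2
      }
    }
    if (n >= 4L) {
      for (i in 4:n) {
        sss <- ssv[(i - 3L):i]
        if (length(unique(sss)) != 1L || is.null(SS_TARGETS[[sss[1L]]]))
          next
        t <- SS_TARGETS[[sss[1L]]]
        dph <- .angDiff(.dihedralDeg(ca[i - 3L, , drop = FALSE],
                                     ca[i - 2L, , drop = FALSE],
                                     ca[i - 1L, , drop = FALSE],
                                     ca[i, , drop = FALSE]),
                        t[["phi"]]) * pi / 180
        e <- e + config$wSS * dph^2
      }
    }
  }
  e
}

#' Total energy with decomposition
#'
#' Computes the four energy components (receptor-peptide interaction,
#' local peptide geometry, excluded volume, contact restraints) and
#' their sum.
#'
#' @inheritParams interactionEnergy
#' @param restraints a [RestraintSet-class] (empty set: zero restraint
#'   component).
#' @param ss optional peptide secondary-structure string.
#' @return an [EnergyBreakdown-class].
#' @export
totalEnergy <- function(complex, restraints = RestraintSet(),
                        potential = contactPotential(), ss = NULL,
                        config = dockConfig()) {
  inter <- interactionEnergy(complex, potential, config)
  intra <- intraPeptideEnergy(complex, ss, config)
  ev <- excludedVolume(complex, config)
  res <- totalRestraintEnergy(complex, restraints)
  new("EnergyBreakdown", interaction = inter, intraPeptide = intra,
      excludedVolume = ev, restraint = res,
      total = inter + intra + ev + res)
}

#' @rdname EnergyBreakdown
#' @param x an [EnergyBreakdown-class].
#' @export
setMethod("energyComponents", "EnergyBreakdown", function(x)
  c(interaction = x@interaction, intraPeptide = x@intraPeptide,
    excludedVolume = x@excludedVolume, restraint = x@restraint,
    total = x@total))

setMethod("show", "EnergyBreakdown", function(object) {
  v <- energyComponents(object)
  cat("EnergyBreakdown (simulation units)\n")
  for (nm in names(v)) cat(sprintf("  %-15s %10.4f\n", nm, v[[nm]]))
  invisible(NULL)
})
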