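#' @import methods
NULL

PEPTIDE_CHAIN <- "PEP"

#' Coarse-grained protein-peptide complex
#'
#' A \code{CGComplex} stores one or more receptor chains plus (optionally)
#' one peptide chain in a reduced representation where every residue is
#' described by up to four pseudo-atoms: the alpha carbon (CA), the beta
#' carbon (CB, absent for glycine), the side-chain heavy-atom center of
#' mass (SC; equal to CA for glycine) and the center of the peptide bond
#' to the following residue (CP; absent for the last residue of a chain).
#' The peptide chain carries the reserved chain label \code{"PEP"}.
#'
#' Residues are stored in chain order; coordinates are plain numeric
#' \code{n x 3} matrices in Angstrom. Rows of \code{cb} and \code{cp} may
#' be \code{NA} where the pseudo-atom is undefined.
#'
#' @slot chain character vector of per-residue chain labels.
#' @slot resno integer vector of author residue numbers.
#' @slot aa character vector of one-letter amino-acid codes.
#' @slot ca,cb,sc,cp numeric \code{n x 3} coordinate matrices (Angstrom).
#'
#' @seealso [coarseGrain()], [buildPeptide()], [makeToyComplex()]
#' @export
setClass("CGComplex",
  representation(chain = "character", resno = "integer", aa = "character",
                 ca = "matrix", cb = "matrix", sc = "matrix",
                 cp = "matrix"))

setMethod("initialize", "CGComplex", function(.Object, ...) {
  .Object <- callNextMethod(.Object, ...)
  for (w in c("ca", "cb", "sc", "cp"))
    dimnames(slot(.Object, w)) <- NULL
  names(.Object@chain) <- NULL
  names(.Object@resno) <- NULL
  names(.Object@aa) <- NULL
  .Object
})

setValidity("CGComplex", function(object) {
  n <- length(object@chain)
  msg <- character()
  if (length(object@resno) != n || length(object@aa) != n)
    msg <- c(msg, "'chain', 'resno' and 'aa' must have equal length")
  for (w in c("ca", "sc"))
    msg <- c(msg, .checkCoordMatrix(slot(object, w), n, w))
  for (w in c("cb", "cp"))
    msg <- c(msg, .checkCoordMatrix(slot(object, w), n, w, allowNA = TRUE))
  if (!all(object@aa %in% AA1))
    msg <- c(msg, sprintf("unknown amino-acid code(s): %s",
                          paste(unique(setdiff(object@aa, AA1)),
                                collapse = ", ")))
  pep <- object@chain == PEPTIDE_CHAIN
  if (any(pep) && sum(pep) < 3L)
    msg <- c(msg, "peptide chain must have at least 3 residues")
  for (ch in unique(object@chain))
    if (anyDuplicated(object@resno[object@chain == ch]))
      msg <- c(msg, sprintf("duplicated residue numbers in chain '%s'", ch))
  msg <- msg[!vapply(msg, is.null, logical(1L))]
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Contact restraint between a receptor and a peptide residue
#'
#' One soft distance restraint between the side-chain centers (SC) of a
#' receptor residue and a peptide residue. The restraint contributes zero
#' energy while the SC-SC distance \code{d} is at most the cutoff
#' \code{d0}, and a linear penalty \code{s * (d - d0)} beyond it. An
#' ambiguous restraint (receptor residue against *any* peptide residue,
#' minimum-distance rule) is encoded with \code{pepResno = NA}.
#'
#' @slot recResno integer receptor residue number.
#' @slot recChain character receptor chain label.
#' @slot pepResno integer peptide residue number, or \code{NA} for an
#'   ambiguous restraint over all peptide residues.
#' @slot d0 numeric cutoff distance in Angstrom (default 5.0).
#' @slot s numeric restraint weight, energy per Angstrom (default 1.0).
#'
#' @seealso [restraintEnergy()], [parseRestraints()]
#' @export
setClass("ContactRestraint",
  representation(recResno = "integer", recChain = "character",
                 pepResno = "integer", d0 = "numeric", s = "numeric"))

setValidity("ContactRestraint", function(object) {
  msg <- character()
  if (length(object@d0) != 1L || !is.finite(object@d0) || object@d0 <= 0)
    msg <- c(msg, "'d0' must be a single positive number")
  if (length(object@s) != 1L || !is.finite(object@s) || object@s < 0)
    msg <- c(msg, "'s' must be a single non-negative number")
  if (length(object@recResno) != 1L || is.na(object@recResno))
    msg <- c(msg, "'recResno' must be a single integer")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Ordered collection of contact restraints
#'
#' @slot restraints list of [ContactRestraint-class] objects. Duplicate
#'   (receptor residue, peptide residue) pairs are rejected.
#' @export
setClass("RestraintSet", representation(restraints = "list"))

setValidity("RestraintSet", function(object) {
  if (!all(vapply(object@restraints, is, logical(1L), "ContactRestraint")))
    return("all elements must be ContactRestraint objects")
  key <- vapply(object@restraints, function(r)
    paste(r@recResno, r@recChain, r@pepResno), character(1L))
  if (anyDuplicated(key))
    return(sprintf("duplicate restraint pair(s): %s",
                   paste(unique(key[duplicated(key)]), collapse = "; ")))
  TRUE
})

#' Energy decomposition of a coarse-grained complex
#'
#' @slot interaction receptor-peptide contact energy (square-well term).
#' @slot intraPeptide local peptide backbone/side-chain term.
#' @slot excludedVolume soft-core repulsion.
#' @slot restraint total contact-restraint energy.
#' @slot total sum of the four components.
#' @export
setClass("EnergyBreakdown",
  representation(interaction = "numeric", intraPeptide = "numeric",
                 excludedVolume = "numeric", restraint = "numeric",
                 total = "numeric"))

setValidity("EnergyBreakdown", function(object) {
  s <- object@interaction + object@intraPeptide + object@excludedVolume +
    object@restraint
  tol <- 1e-9 * max(1, abs(s))
  if (abs(object@total - s) > tol)
    return("'total' must equal the sum of the components")
  TRUE
})

#' Docking trajectory
#'
#' Ordered set of sampled complex conformations together with per-model
#' energy decompositions, replica/sweep provenance and the per-restraint
#' SC-SC distances recorded at snapshot time (so that downstream contact
#' filtering needs no recomputation).
#'
#' @slot template [CGComplex-class] giving the residue topology shared by
#'   all models.
#' @slot ca,cb,sc,cp numeric arrays of dimension \code{n_res x 3 x
#'   n_models} holding per-model pseudo-atom coordinates.
#' @slot energies data.frame with one row per model: \code{model},
#'   \code{replica}, \code{sweep}, \code{interaction},
#'   \code{intraPeptide}, \code{excludedVolume}, \code{restraint},
#'   \code{total}.
#' @slot restraintDistances numeric \code{n_models x n_restraints} matrix.
#' @slot restraints the [RestraintSet-class] the distances refer to.
#' @slot modelIndex integer original model indices (tracks subsetting).
#' @export
setClass("Trajectory",
  representation(template = "CGComplex", ca = "array", cb = "array",
                 sc = "array", cp = "array", energies = "data.frame",
                 restraintDistances = "matrix",
                 restraints = "RestraintSet", modelIndex = "integer"))

setValidity("Trajectory", function(object) {
  n <- length(object@template@chain)
  m <- nrow(object@energies)
  msg <- character()
  for (w in c("ca", "cb", "sc", "cp")) {
    d <- dim(slot(object, w))
    if (length(d) != 3L || d[1L] != n || d[2L] != 3L || d[3L] != m)
      msg <- c(msg, sprintf("'%s' must be a %d x 3 x %d array", w, n, m))
  }
  if (nrow(object@restraintDistances) != m &&
      length(object@restraints@restraints) > 0L)
    msg <- c(msg, "one row of restraint distances per model required")
  if (length(object@modelIndex) != m)
    msg <- c(msg, "'modelIndex' must have one entry per model")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Clustering report over filtered docking models
#'
#' Result of k-medoids clustering on the pairwise peptide-RMSD matrix of
#' an (already filtered) trajectory, with per-cluster density scores and
#' the ordered list of final representative models.
#'
#' @slot assignment integer cluster id per clustered model.
#' @slot medoids integer medoid positions (within the clustered subset).
#' @slot density numeric per-cluster density score (size / mean
#'   intra-cluster pairwise peptide-RMSD; size for singletons).
#' @slot finalModels integer positions of the final models within the
#'   clustered trajectory, ordered by decreasing density.
#' @slot trajectory the clustered (filtered) [Trajectory-class].
#' @slot provenance list of per-stage model counts for the full pipeline.
#' @export
setClass("ClusterReport",
  representation(assignment = "integer", medoids = "integer",
                 density = "numeric", finalModels = "integer",
                 trajectory = "Trajectory", provenance = "list"))

#' Specification of a procedurally generated toy docking system
#'
#' @slot receptorSize integer total receptor residues (split over three
#'   straight chains forming a groove).
#' @slot pocketDepth numeric depth of the binding groove in Angstrom.
#' @slot peptideLength integer peptide residues.
#' @slot nPlantedContacts integer number of receptor-peptide SC-SC
#'   contacts planted at known distances below 5 Angstrom.
#' @slot seed integer RNG seed making the system deterministic.
#' @export
setClass("ToySystemSpec",
  representation(receptorSize = "integer", pocketDepth = "numeric",
                 peptideLength = "integer", nPlantedContacts = "integer",
                 seed = "integer"))

setValidity("ToySystemSpec", function(object) {
  msg <- character()
  if (object@nPlantedContacts > object@peptideLength)
    msg <- c(msg, "cannot plant more contacts than peptide residues")
  if (object@peptideLength < 3L)
    msg <- c(msg, "peptide must have at least 3 residues")
  if (object@receptorSize < 9L)
    msg <- c(msg, "receptor needs at least 9 residues (3 per chain)")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
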