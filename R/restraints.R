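## Contact-restraint input grammar, the linear flat-bottom restraint
## energy term, ambiguous restraints and native-contact extraction.

DEFAULT_D0 <- 5.0   # default restraint cutoff, Angstrom
DEFAULT_S <- 1.0    # default restraint weight, energy per Angstrom
NATIVE_CONTACT_CUTOFF <- 5.0  # SC-SC distance below which residues are
                              # in contact (strict <)

#' Create a contact restraint
#'
#' @param recResno receptor residue number.
#' @param recChain receptor chain label.
#' @param pepResno peptide residue number, or \code{NA} for an ambiguous
#'   restraint against all peptide residues (minimum-distance rule).
#' @param d0 cutoff distance in Angstrom below which the restraint
#'   contributes no energy (default 5.0).
#' @param s restraint weight: the slope, in energy per Angstrom, of the
#'   linear penalty beyond \code{d0} (default 1.0).
#' @return a [ContactRestraint-class].
#' @examples
#' contactRestraint(1060, "C", 6)           # defaults d0 = 5, s = 1
#' @export
contactRestraint <- function(recResno, recChain, pepResno = NA,
                             d0 = DEFAULT_D0, s = DEFAULT_S) {
  new("ContactRestraint", recResno = as.integer(recResno),
      recChain = as.character(recChain), pepResno = as.integer(pepResno),
      d0 = as.numeric(d0), s = as.numeric(s))
}

#' Create a restraint set
#'
#' @param ... [ContactRestraint-class] objects (or a single list of
#'   them).
#' @return a [RestraintSet-class].
#' @export
RestraintSet <- function(...) {
  r <- list(...)
  if (length(r) == 1L && is.list(r[[1L]]) && !is(r[[1L]], "ContactRestraint"))
    r <- r[[1L]]
  new("RestraintSet", restraints = r)
}

setMethod("length", "RestraintSet", function(x) length(x@restraints))

setMethod("[[", "RestraintSet", function(x, i) x@restraints[[i]])

setMethod("show", "ContactRestraint", function(object) {
  cat("ContactRestraint:", formatRestraint(object), "\n")
  invisible(NULL)
})

setMethod("show", "RestraintSet", function(object) {
  cat(sprintf("RestraintSet with %d restraint(s)\n", length(object)))
  for (r in object@restraints) cat(" ", formatRestraint(r), "\n")
  invisible(NULL)
})

#' @rdname parseRestraints
#' @export
setMethod("as.data.frame", "RestraintSet", function(x, ...) {
  if (length(x) == 0L)
    return(data.frame(recResno = integer(), recChain = character(),
                      pepResno = integer(), d0 = numeric(),
                      s = numeric()))
  do.call(rbind, lapply(x@restraints, function(r)
    data.frame(recResno = r@recResno, recChain = r@recChain,
               pepResno = r@pepResno, d0 = r@d0, s = r@s)))
})

#' Parse contact-restraint input
#'
#' One restraint is written as
#' \preformatted{<residue1number>:<chainID> <residue2number>:PEP <cutoff> <weight>}
#' where the peptide side must carry the reserved chain id \code{PEP}.
#' Cutoff and weight may be omitted (both, or only the weight), in which
#' case the defaults \code{d0 = 5.0} Angstrom and \code{s = 1.0} apply,
#' so \code{"1060:C 6:PEP 5.0 1.0"}, \code{"1060:C 6:PEP 5.0"} and
#' \code{"1060:C 6:PEP"} are equivalent. Multiple restraints are
#' separated by newlines or semicolons. An ambiguous restraint
#' (receptor residue against any peptide residue) uses \code{ALL} in
#' place of the peptide residue number.
#'
#' @param text restraint text: one or more lines / semicolon-separated
#'   segments.
#' @param line a single restraint line.
#' @param x a [RestraintSet-class].
#' @param restraint a [ContactRestraint-class].
#' @param ... unused.
#' @return [parseRestraints()] returns a [RestraintSet-class];
#'   [parseRestraintLine()] a [ContactRestraint-class];
#'   [formatRestraint()] the canonical four-token line.
#' @examples
#' parseRestraints("1060:C 6:PEP 5.0 1.0;1066:C 7:PEP 5.0 1.0")
#' @export
parseRestraints <- function(text) {
  segs <- trimws(unlist(strsplit(paste(text, collapse = "\n"), "[\n;]")))
  segs <- segs[nzchar(segs)]
  RestraintSet(lapply(segs, function(s)
    tryCatch(parseRestraintLine(s), error = function(e)
      stop(sprintf("malformed restraint segment '%s': %s", s,
                   conditionMessage(e)), call. = FALSE))))
}

#' @rdname parseRestraints
#' @export
parseRestraintLine <- function(line) {
  tok <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
  if (length(tok) < 2L || length(tok) > 4L)
    stop("expected 2 to 4 whitespace-separated tokens")
  m1 <- regmatches(tok[1L], regexec("^([0-9]+):(\\S+)$", tok[1L]))[[1L]]
  if (length(m1) != 3L)
    stop("first token must be <residuenumber>:<chainID>")
  if (toupper(m1[3L]) == "PEP")
    stop("first token must reference a receptor residue, not PEP")
  m2 <- regmatches(toupper(tok[2L]),
                   regexec("^([0-9]+|ALL):PEP$",
                           toupper(tok[2L])))[[1L]]
  if (length(m2) != 2L)
    stop("second token must be <residuenumber>:PEP (or ALL:PEP)")
  num <- function(t, what) {
    v <- suppressWarnings(as.numeric(t))
    if (is.na(v)) stop(sprintf("non-numeric %s '%s'", what, t))
    if (v < 0) stop(sprintf("negative %s '%s'", what, t))
    v
  }
  d0 <- if (length(tok) >= 3L) num(tok[3L], "cutoff") else DEFAULT_D0
  s <- if (length(tok) == 4L) num(tok[4L], "weight") else DEFAULT_S
  if (d0 <= 0) stop("cutoff must be positive")
  contactRestraint(as.integer(m1[2L]), m1[3L],
                   if (m2[2L] == "ALL") NA else as.integer(m2[2L]),
                   d0, s)
}

#' @rdname parseRestraints
#' @export
formatRestraint <- function(restraint) {
  fmt <- function(v) format(v, nsmall = 1, trim = TRUE)
  sprintf("%d:%s %s:PEP %s %s", restraint@recResno, restraint@recChain,
          if (is.na(restraint@pepResno)) "ALL"
          else as.character(restraint@pepResno),
          fmt(restraint@d0), fmt(restraint@s))
}

#' @rdname parseRestraints
#' @export
formatRestraints <- function(x)
  vapply(x@restraints, formatRestraint, character(1L))

#' Contact-restraint energy term
#'
#' The restraint energy as a function of the SC-SC distance \code{d}:
#' zero for \code{d <= d0} (peptide motion is unaffected below the
#' cutoff) and \code{s * (d - d0)} beyond it, i.e. a linear penalty with
#' slope \code{s}. The default parameters (\code{d0 = 5} Angstrom,
#' \code{s = 1}) give a soft restraint that leaves the peptide fully
#' flexible within the binding site.
#'
#' @param d SC-SC distance(s) in Angstrom (vectorized).
#' @param restraint optional [ContactRestraint-class] supplying
#'   \code{d0} and \code{s}.
#' @param d0,s cutoff and weight used when no restraint is given.
#' @return numeric energy, same length as \code{d}.
#' @examples
#' restraintEnergy(7.3, d0 = 5, s = 1)  # 2.3
#' restraintEnergy(5.0)                 # 0 at the boundary
#' @export
restraintEnergy <- function(d, restraint = NULL, d0 = DEFAULT_D0,
                            s = DEFAULT_S) {
  if (!is.null(restraint)) {
    d0 <- restraint@d0
    s <- restraint@s
  }
  stopifnot(all(d >= 0))
  s * pmax(0, d - d0)
}

#' SC-SC distance of a restraint in a complex
#'
#' Euclidean distance between the side-chain-center pseudo-atoms of the
#' restrained receptor and peptide residues. For an ambiguous restraint
#' the minimum over all peptide residues is returned.
#'
#' @param complex a [CGComplex-class] with a peptide chain.
#' @param restraint a [ContactRestraint-class].
#' @return distance in Angstrom.
#' @export
restraintDistance <- function(complex, restraint) {
  i <- .residueIndex(complex, restraint@recResno, restraint@recChain)
  if (is.na(restraint@pepResno)) {
    pep <- scCoords(complex, PEPTIDE_CHAIN)
    if (nrow(pep) == 0L) stop("complex has no peptide chain")
    min(sqrt(colSums((t(pep) - complex@sc[i, ])^2)))
  } else {
    j <- .residueIndex(complex, restraint@pepResno, PEPTIDE_CHAIN)
    sqrt(sum((complex@sc[i, ] - complex@sc[j, ])^2))
  }
}

#' Total restraint energy of a complex
#'
#' Sum of [restraintEnergy()] over all restraints of the set, evaluated
#' at the current SC-SC distances; zero for an empty set.
#'
#' @param complex a [CGComplex-class].
#' @param restraints a [RestraintSet-class].
#' @return numeric energy.
#' @export
totalRestraintEnergy <- function(complex, restraints) {
  if (length(restraints) == 0L) return(0)
  sum(vapply(restraints@restraints, function(r)
    restraintEnergy(restraintDistance(complex, r), r), numeric(1L)))
}

#' Ambiguous restraint on a receptor residue
#'
#' Builds the ambiguous-restraint input used when only a receptor
#' residue is known: a single restraint against all peptide residues
#' (minimum-distance rule) with the cutoff set to the number of peptide
#' residues plus 12, in Angstrom.
#'
#' @param recResno,recChain receptor residue.
#' @param peptideLength number of peptide residues (>= 3).
#' @param s restraint weight (default 1.0).
#' @return a [RestraintSet-class] with one ambiguous restraint.
#' @examples
#' ambiguousRestraints(1060, "C", peptideLength = 6)  # d0 = 18 A
#' @export
ambiguousRestraints <- function(recResno, recChain, peptideLength,
                                s = DEFAULT_S) {
  stopifnot(peptideLength >= 3L)
  RestraintSet(contactRestraint(recResno, recChain, NA,
                                d0 = peptideLength + 12, s = s))
}

#' Extract native contacts from a reference complex
#'
#' A receptor-peptide residue pair is in contact when the distance
#' between their side-chain centers (SC) is strictly below 5 Angstrom.
#'
#' @param reference a [CGComplex-class] with receptor and peptide.
#' @param cutoff contact cutoff in Angstrom (default 5).
#' @return data.frame with columns \code{recResno}, \code{recChain},
#'   \code{pepResno}, \code{distance}, sorted by distance (ascending).
#' @export
nativeContacts <- function(reference, cutoff = NATIVE_CONTACT_CUTOFF) {
  if (!hasPeptide(reference)) stop("reference has no peptide chain")
  recIdx <- which(reference@chain != PEPTIDE_CHAIN)
  pepIdx <- which(reference@chain == PEPTIDE_CHAIN)
  d <- sqrt(.crossDist2(reference@sc[recIdx, , drop = FALSE],
                        reference@sc[pepIdx, , drop = FALSE]))
  hit <- which(d < cutoff, arr.ind = TRUE)
  out <- data.frame(
    recResno = reference@resno[recIdx[hit[, 1L]]],
    recChain = reference@chain[recIdx[hit[, 1L]]],
    pepResno = reference@resno[pepIdx[hit[, 2L]]],
    distance = d[hit], stringsAsFactors = FALSE)
  out[order(out$distance), , drop = FALSE]
}

#' Pick one native contact at random
#'
#' Chooses a contact uniformly from a native-contact table (as returned
#' by [nativeContacts()]) and converts it to a default-parameter
#' restraint (\code{d0 = 5.0}, \code{s = 1.0}). Deterministic for a
#' fixed seed.
#'
#' @param contacts data.frame from [nativeContacts()].
#' @param seed integer RNG seed.
#' @return a [ContactRestraint-class].
#' @export
pickNativeContact <- function(contacts, seed = 1L) {
  if (nrow(contacts) == 0L) stop("no native contacts to pick from")
  i <- .withSeed(seed, sample.int(nrow(contacts), 1L))
  contactRestraint(contacts$recResno[i], contacts$recChain[i],
                   contacts$pepResno[i])
}
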