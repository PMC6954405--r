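## Model-quality assessment against a reference complex: optimal
## superposition, peptide-RMSD, interface-RMSD, restraint-violation
## profiles and accuracy categories.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation and translation mapping \code{mobile} onto
#' \code{target} for paired coordinate sets, via singular value
#' decomposition with the proper-rotation (det = +1) correction. The
#' returned RMSD is the minimum over all rigid transforms.
#'
#' @param mobile,target numeric \code{n x 3} matrices of paired points
#'   (n >= 3).
#' @return list with \code{rotation} (3 x 3, to be applied to row
#'   vectors as \code{x \%*\% rotation}), \code{translation} (length
#'   3), and \code{rmsd}. The transformed mobile set is
#'   \code{mobile \%*\% rotation + translation}.
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' superpose(a, a)$rmsd  # 0
#' @export
superpose <- function(mobile, target) {
  stopifnot(is.matrix(mobile), is.matrix(target),
            ncol(mobile) == 3L, ncol(target) == 3L,
            nrow(mobile) == nrow(target))
  if (nrow(mobile) < 3L)
    stop("superposition requires at least 3 paired points")
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  M <- sweep(mobile, 2L, cm)
  T_ <- sweep(target, 2L, ct)
  s <- svd(crossprod(M, T_))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  moved <- M %*% R
  rmsd <- sqrt(mean(rowSums((moved - T_)^2)))
  list(rotation = R, translation = ct - as.vector(cm %*% R),
       rmsd = rmsd)
}

.applyTransform <- function(x, fit)
  x %*% fit$rotation + rep(fit$translation, each = nrow(x))

## Match receptor residues of model and reference by (chain, resno);
## errors list the unmatched residues.
.matchReceptor <- function(model, reference) {
  km <- paste(model@chain, model@resno)[model@chain != PEPTIDE_CHAIN]
  kr <- paste(reference@chain,
              reference@resno)[reference@chain != PEPTIDE_CHAIN]
  onlyM <- setdiff(km, kr)
  onlyR <- setdiff(kr, km)
  if (length(onlyM) || length(onlyR))
    stop("receptor residue mismatch between model and reference; ",
         "unmatched: ",
         paste(c(onlyM, onlyR), collapse = ", "))
  keyAll <- paste(model@chain, model@resno)
  keyRef <- paste(reference@chain, reference@resno)
  list(model = match(km, keyAll), reference = match(km, keyRef))
}

#' Peptide-RMSD of a model against a reference complex
#'
#' RMSD of the peptide CA atoms computed after optimal superposition of
#' the model receptor onto the reference receptor (the superposition is
#' fitted on receptor CA atoms only and then applied to the model
#' peptide; no further fitting). Peptide residues are paired by
#' sequence position.
#'
#' @param model,reference [CGComplex-class] objects sharing receptor
#'   residue numbering and peptide length.
#' @return peptide-RMSD in Angstrom.
#' @export
peptideRMSD <- function(model, reference) {
  idx <- .matchReceptor(model, reference)
  pm <- caCoords(model, PEPTIDE_CHAIN)
  pr <- caCoords(reference, PEPTIDE_CHAIN)
  if (nrow(pm) != nrow(pr))
    stop(sprintf("peptide length differs: %d (model) vs %d (reference)",
                 nrow(pm), nrow(pr)))
  fit <- superpose(model@ca[idx$model, , drop = FALSE],
                   reference@ca[idx$reference, , drop = FALSE])
  sqrt(mean(rowSums((.applyTransform(pm, fit) - pr)^2)))
}

## Receptor residues of the reference with any pseudo-atom within
## `cutoff` of any reference-peptide pseudo-atom.
.interfaceResidues <- function(reference, cutoff) {
  recIdx <- which(reference@chain != PEPTIDE_CHAIN)
  pepIdx <- which(reference@chain == PEPTIDE_CHAIN)
  stack <- function(idx) {
    m <- rbind(reference@ca[idx, , drop = FALSE],
               reference@cb[idx, , drop = FALSE],
               reference@sc[idx, , drop = FALSE],
               reference@cp[idx, , drop = FALSE])
    who <- rep(idx, 4L)
    ok <- !is.na(m[, 1L])
    list(xyz = m[ok, , drop = FALSE], who = who[ok])
  }
  rec <- stack(recIdx)
  pep <- stack(pepIdx)
  d2 <- .crossDist2(rec$xyz, pep$xyz)
  near <- rec$who[rowSums(d2 <= cutoff^2) > 0L]
  sort(unique(near))
}

#' Interface-RMSD of a model against a reference complex
#'
#' The interface is defined on the reference: receptor residues with
#' any pseudo-atom within \code{cutoff} (default 10 Angstrom, the CAPRI
#' convention) of any reference-peptide pseudo-atom, plus all peptide
#' residues. The model is superposed onto the reference on the CA atoms
#' of these interface residues and the RMSD is computed over the same
#' atoms.
#'
#' @inheritParams peptideRMSD
#' @param cutoff interface distance cutoff in Angstrom (default 10).
#' @return i-RMSD in Angstrom, or \code{NA} (with a warning) when the
#'   reference interface is empty.
#' @export
interfaceRMSD <- function(model, reference, cutoff = 10) {
  idx <- .matchReceptor(model, reference)
  ifRes <- .interfaceResidues(reference, cutoff)
  if (length(ifRes) == 0L) {
    warning("empty interface: no receptor residue within ", cutoff,
            " Angstrom of the reference peptide; i-RMSD undefined")
    return(NA_real_)
  }
  keyRef <- paste(reference@chain, reference@resno)
  keyMod <- paste(model@chain, model@resno)
  want <- c(keyRef[ifRes],
            keyRef[reference@chain == PEPTIDE_CHAIN])
  im <- match(want, keyMod)
  ir <- match(want, keyRef)
  if (anyNA(im))
    stop("interface residues missing from model: ",
         paste(want[is.na(im)], collapse = ", "))
  fit <- superpose(model@ca[im, , drop = FALSE],
                   reference@ca[ir, , drop = FALSE])
  fit$rmsd
}

#' Accuracy categories for docking models
#'
#' Peptide-RMSD categories: high-accuracy (peptide-RMSD < 3 Angstrom),
#' medium-accuracy (3 <= peptide-RMSD <= 5.5) and low-accuracy
#' (peptide-RMSD > 5.5). Interface-RMSD categories: sub-Angstrom
#' (i-RMSD <= 1), near-native (1 < i-RMSD <= 2) and not acceptable
#' (i-RMSD > 2).
#'
#' @param peptideRmsd numeric vector of peptide-RMSD values (Angstrom).
#' @param iRmsd optional numeric vector of interface-RMSD values.
#' @return data.frame with \code{peptideRmsd}, \code{categoryRmsd} and,
#'   when \code{iRmsd} is given, \code{iRmsd} and \code{categoryIrmsd}.
#' @examples
#' classifyQuality(c(2.41, 3.0, 13.47))$categoryRmsd
#' @export
classifyQuality <- function(peptideRmsd, iRmsd = NULL) {
  stopifnot(all(peptideRmsd >= 0, na.rm = TRUE))
  cat1 <- ifelse(peptideRmsd < 3, "high",
                 ifelse(peptideRmsd <= 5.5, "medium", "low"))
  out <- data.frame(peptideRmsd = peptideRmsd,
                    categoryRmsd = factor(cat1, c("high", "medium",
                                                  "low")))
  if (!is.null(iRmsd)) {
    cat2 <- ifelse(iRmsd <= 1, "sub_angstrom",
                   ifelse(iRmsd <= 2, "near_native", "not_acceptable"))
    out$iRmsd <- iRmsd
    out$categoryIrmsd <- factor(cat2, c("sub_angstrom", "near_native",
                                        "not_acceptable"))
  }
  out
}

#' Per-model restraint-violation profile
#'
#' For every model and restraint, the distance above the cutoff:
#' \code{max(0, d - d0)} in Angstrom, where \code{d} is the recorded
#' SC-SC distance. Zero encodes "within the cutoff".
#'
#' @param trajectory a [Trajectory-class].
#' @param restraints the [RestraintSet-class] (default: the
#'   trajectory's own).
#' @return numeric \code{n_models x n_restraints} matrix.
#' @export
violationProfile <- function(trajectory,
                             restraints = restraintSet(trajectory)) {
  d0 <- vapply(restraints@restraints, function(r) r@d0, numeric(1L))
  v <- sweep(restraintDistances(trajectory), 2L, d0)
  v[v < 0] <- 0
  v
}

#' Evaluate trajectory models against a reference complex
#'
#' Computes peptide-RMSD, interface-RMSD, per-restraint violations and
#' accuracy categories for every model of a trajectory.
#'
#' @param trajectory a [Trajectory-class].
#' @param reference the reference [CGComplex-class].
#' @param iRmsd logical: also compute interface-RMSD (slower)?
#' @return data.frame with one row per model.
#' @export
evaluateModels <- function(trajectory, reference, iRmsd = FALSE) {
  m <- nModels(trajectory)
  prmsd <- vapply(seq_len(m), function(i)
    peptideRMSD(getModel(trajectory, i), reference), numeric(1L))
  ir <- if (iRmsd) vapply(seq_len(m), function(i)
    interfaceRMSD(getModel(trajectory, i), reference), numeric(1L))
    else NULL
  out <- classifyQuality(prmsd, ir)
  out <- cbind(data.frame(model = trajectory@modelIndex), out)
  viol <- violationProfile(trajectory)
  if (ncol(viol) > 0L) {
    colnames(viol) <- paste0("violation.", seq_len(ncol(viol)))
    out <- cbind(out, as.data.frame(viol))
  }
  out
}

#' Summarize best-model quality over benchmark cases
#'
#' For every case, the best (lowest peptide-RMSD) model within the full
#' model set and within the top-scored subset determines the case's
#' category; the summary reports the fraction of cases per category for
#' both sets.
#'
#' @param cases list; each element is a list with numeric vectors
#'   \code{all} (peptide-RMSDs of all models) and \code{top}
#'   (peptide-RMSDs of the top-scored models).
#' @return data.frame with columns \code{set}, \code{high},
#'   \code{medium}, \code{low} (fractions over cases).
#' @export
summarizeBenchmark <- function(cases) {
  frac <- function(rmsds) {
    best <- vapply(rmsds, min, numeric(1L))
    cat <- classifyQuality(best)$categoryRmsd
    as.vector(table(cat)) / length(best)
  }
  all_ <- frac(lapply(cases, `[[`, "all"))
  top <- frac(lapply(cases, `[[`, "top"))
  data.frame(set = c("all", "top"),
             high = c(all_[1L], top[1L]),
             medium = c(all_[2L], top[2L]),
             low = c(all_[3L], top[3L]))
}
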