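## Serialization of CG models as standard PDB files (pseudo-atom names
## CA / CB / SC / CP, MODEL blocks for multi-model files) plus the CSV
## sidecar carrying per-model energies and restraint distances.

.aa123 <- function(one) bio3d::aa123(one)

.pepChainChar <- function(x) {
  used <- setdiff(unique(x@chain), PEPTIDE_CHAIN)
  cand <- c("P", setdiff(LETTERS, used))
  setdiff(cand, used)[1L]
}

.cgAtomLines <- function(x, pepChar, serialStart = 1L) {
  lines <- character(0)
  serial <- serialStart
  for (i in seq_len(length(x))) {
    ch <- if (x@chain[i] == PEPTIDE_CHAIN) pepChar else x@chain[i]
    res3 <- .aa123(x@aa[i])
    for (nm in c("CA", "CB", "SC", "CP")) {
      xyz <- switch(nm, CA = x@ca[i, ], CB = x@cb[i, ],
                    SC = x@sc[i, ], CP = x@cp[i, ])
      if (anyNA(xyz)) next
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        serial %% 100000L, nm, res3, ch, x@resno[i],
        xyz[1L], xyz[2L], xyz[3L]))
      serial <- serial + 1L
    }
  }
  lines
}

#' Write coarse-grained models to a PDB file
#'
#' Models are written as standard PDB ATOM records with pseudo-atom names
#' \code{CA}, \code{CB}, \code{SC} and \code{CP}; multiple models are
#' wrapped in \code{MODEL}/\code{ENDMDL} blocks. Because the PDB chain
#' field holds a single character, the peptide chain is written under a
#' free chain letter (preferring \code{P}) recorded in a
#' \code{REMARK  99 PEPTIDE CHAIN} header that [readCGPDB()] uses to
#' restore the reserved \code{"PEP"} label.
#'
#' @param x a [CGComplex-class] or a list of them (shared topology).
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeCGPDB <- function(x, file) {
  if (is(x, "CGComplex")) x <- list(x)
  pepChar <- .pepChainChar(x[[1L]])
  out <- character(0)
  if (hasPeptide(x[[1L]]))
    out <- sprintf("REMARK  99 PEPTIDE CHAIN %s", pepChar)
  multi <- length(x) > 1L
  for (m in seq_along(x)) {
    if (multi) out <- c(out, sprintf("MODEL %8d", m))
    out <- c(out, .cgAtomLines(x[[m]], pepChar))
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, file)
  invisible(file)
}

#' Read coarse-grained models from a PDB file written by [writeCGPDB()]
#'
#' @param file path to a CG PDB file.
#' @return a [CGComplex-class], or a list of them for multi-model files.
#' @export
readCGPDB <- function(file) {
  lines <- readLines(file)
  pepChar <- NA_character_
  rem <- grep("^REMARK  99 PEPTIDE CHAIN ", lines, value = TRUE)
  if (length(rem)) pepChar <- trimws(sub("^REMARK  99 PEPTIDE CHAIN ",
                                         "", rem[1L]))
  isModel <- grepl("^MODEL", lines)
  modelId <- cumsum(isModel)
  isAtom <- grepl("^ATOM  ", lines)
  if (!any(isAtom)) stop("no ATOM records in ", file)
  if (!any(isModel)) modelId <- rep(1L, length(lines))
  modelId[modelId == 0L] <- 1L

  parseModel <- function(ln) {
    name <- trimws(substr(ln, 13L, 16L))
    res3 <- trimws(substr(ln, 18L, 20L))
    ch <- substr(ln, 22L, 22L)
    resno <- as.integer(substr(ln, 23L, 26L))
    xyz <- cbind(as.numeric(substr(ln, 31L, 38L)),
                 as.numeric(substr(ln, 39L, 46L)),
                 as.numeric(substr(ln, 47L, 54L)))
    key <- paste(ch, resno)
    ukey <- unique(key)
    n <- length(ukey)
    first <- match(ukey, key)
    chain <- ch[first]
    if (!is.na(pepChar)) chain[chain == pepChar] <- PEPTIDE_CHAIN
    ca <- cb <- sc <- cp <- matrix(NA_real_, n, 3L)
    row <- match(key, ukey)
    for (slotName in c("CA", "CB", "SC", "CP")) {
      hit <- name == slotName
      m <- switch(slotName, CA = "ca", CB = "cb", SC = "sc", CP = "cp")
      tmp <- get(m)
      tmp[row[hit], ] <- xyz[hit, , drop = FALSE]
      assign(m, tmp)
    }
    new("CGComplex", chain = chain, resno = resno[first],
        aa = unname(vapply(res3[first], bio3d::aa321, character(1L))),
        ca = ca, cb = cb, sc = sc, cp = cp)
  }

  models <- lapply(split(lines[isAtom], modelId[isAtom]), parseModel)
  names(models) <- NULL
  if (length(models) == 1L) models[[1L]] else models
}

#' Write a docking trajectory as a PDB / CSV pair
#'
#' The conformations go to a multi-model CG PDB file and the per-model
#' bookkeeping (replica, sweep, energy decomposition, per-restraint
#' SC-SC distances) to a CSV sidecar.
#'
#' @param trajectory a [Trajectory-class].
#' @param pdbFile,csvFile output paths.
#' @return invisibly, a list with both paths.
#' @export
writeTrajectory <- function(trajectory, pdbFile, csvFile) {
  m <- nModels(trajectory)
  writeCGPDB(lapply(seq_len(m), function(i) getModel(trajectory, i)),
             pdbFile)
  tab <- trajectory@energies
  rd <- trajectory@restraintDistances
  if (ncol(rd) > 0L) {
    colnames(rd) <- paste0("rdist.", seq_len(ncol(rd)))
    tab <- cbind(tab, as.data.frame(rd))
  }
  utils::write.csv(tab, csvFile, row.names = FALSE)
  invisible(list(pdb = pdbFile, csv = csvFile))
}

#' Read a trajectory written by [writeTrajectory()]
#'
#' @param pdbFile,csvFile paths written by [writeTrajectory()].
#' @param restraints the [RestraintSet-class] the recorded distances
#'   refer to (optional; empty by default).
#' @return a [Trajectory-class].
#' @export
readTrajectory <- function(pdbFile, csvFile,
                           restraints = RestraintSet()) {
  models <- readCGPDB(pdbFile)
  if (is(models, "CGComplex")) models <- list(models)
  tab <- utils::read.csv(csvFile)
  rcols <- grep("^rdist\\.", names(tab))
  rd <- as.matrix(tab[, rcols, drop = FALSE])
  dimnames(rd) <- NULL
  .trajectoryFromModels(models, tab[, setdiff(names(tab),
                                              names(tab)[rcols]),
                                    drop = FALSE],
                        rd, restraints)
}

.trajectoryFromModels <- function(models, energies, rdist, restraints) {
  n <- length(models[[1L]])
  m <- length(models)
  arr <- function(getter)
    array(vapply(models, getter, matrix(0, n, 3L)), dim = c(n, 3L, m))
  new("Trajectory", template = models[[1L]],
      ca = arr(function(x) x@ca), cb = arr(function(x) x@cb),
      sc = arr(function(x) x@sc), cp = arr(function(x) x@cp),
      energies = energies, restraintDistances = rdist,
      restraints = restraints,
      modelIndex = if ("model" %in% names(energies))
        as.integer(energies$model) else seq_len(m))
}
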