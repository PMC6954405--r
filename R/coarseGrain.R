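## Conversion from all-atom PDB input to the coarse-grained representation.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Convert an all-atom structure to coarse-grained representation
#'
#' Reduces every residue of a protein structure to the four pseudo-atoms
#' of the coarse-grained chain model: CA (taken from the input), CB
#' (taken from the input; absent for glycine), SC (unweighted mean of the
#' side-chain heavy atoms, CB included; CA for glycine) and CP (midpoint
#' of the peptide bond \code{C(i)-N(i+1)}; midpoint of the two CA atoms
#' when either backbone atom is missing; absent for the last residue of a
#' chain).
#'
#' Hydrogens are ignored. Alternate locations are resolved by keeping the
#' highest-occupancy conformer (ties broken by file order). HETATM
#' records are dropped, except selenomethionine (MSE), which is treated
#' as methionine.
#'
#' @param pdb path to a PDB file, or a \code{pdb} object from
#'   [bio3d::read.pdb()].
#' @param peptideChain chain label of the peptide chain, or the peptide's
#'   one-letter sequence (matched against each chain); \code{NULL} for a
#'   receptor-only structure.
#' @param aaMap optional named character vector mapping non-standard
#'   three-letter residue names to one-letter codes (e.g.
#'   \code{c(SEP = "S")}); unknown residue names are an error otherwise.
#' @return a [CGComplex-class].
#' @examples
#' f <- system.file("extdata", "example_tripeptide.pdb",
#'                  package = "CGPepDock")
#' if (nzchar(f)) coarseGrain(f)
#' @export
coarseGrain <- function(pdb, peptideChain = NULL, aaMap = NULL) {
  if (is.character(pdb))
    pdb <- bio3d::read.pdb(pdb, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom

  ## selenomethionine -> methionine; drop other heteroatoms
  mse <- at$resid == "MSE"
  at$resid[mse] <- "MET"
  at$type[mse] <- "ATOM"
  at <- at[at$type == "ATOM", , drop = FALSE]

  ## drop hydrogens / deuteriums
  elesy <- if ("elesy" %in% names(at)) toupper(trimws(at$elesy)) else ""
  isH <- elesy %in% c("H", "D") |
    (!nzchar(elesy) & grepl("^[0-9]*[HD]", trimws(at$elety)))
  at <- at[!isH, , drop = FALSE]
  if (nrow(at) == 0L) stop("no protein atoms found in input")

  ## altloc: keep the highest-occupancy conformer per atom, tie -> first
  occ <- at$o
  occ[is.na(occ)] <- 1
  rowid <- seq_len(nrow(at))
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  ord <- order(key, -occ, rowid)
  keep <- ord[!duplicated(key[ord])]
  at <- at[sort(keep), , drop = FALSE]

  rkey <- paste(at$chain, at$resno, at$insert)
  rkey <- factor(rkey, levels = unique(rkey))
  idx <- split(seq_len(nrow(at)), rkey)

  n <- length(idx)
  chain <- character(n); resno <- integer(n); aa <- character(n)
  ca <- cb <- sc <- matrix(NA_real_, n, 3L)
  Cpos <- Npos <- matrix(NA_real_, n, 3L)

  for (k in seq_len(n)) {
    rows <- at[idx[[k]], , drop = FALSE]
    chain[k] <- rows$chain[1L]
    resno[k] <- rows$resno[1L]
    one <- suppressWarnings(bio3d::aa321(rows$resid[1L]))
    if (is.na(one) || one == "X") {
      if (!is.null(aaMap) && rows$resid[1L] %in% names(aaMap))
        one <- aaMap[[rows$resid[1L]]]
      else
        stop(sprintf("unknown residue name '%s' at %s %d%s",
                     rows$resid[1L], chain[k], resno[k],
                     trimws(rows$insert[1L])))
    }
    aa[k] <- one
    xyz <- as.matrix(rows[, c("x", "y", "z")])
    name <- trimws(rows$elety)
    ia <- match("CA", name)
    if (is.na(ia))
      stop(sprintf("missing CA atom for residue %s %d (%s)",
                   chain[k], resno[k], rows$resid[1L]))
    ca[k, ] <- xyz[ia, ]
    ib <- match("CB", name)
    if (!is.na(ib)) cb[k, ] <- xyz[ib, ]
    side <- !(name %in% BACKBONE_ATOMS)
    sc[k, ] <- if (any(side)) colMeans(xyz[side, , drop = FALSE]) else ca[k, ]
    ic <- match("C", name); inn <- match("N", name)
    if (!is.na(ic)) Cpos[k, ] <- xyz[ic, ]
    if (!is.na(inn)) Npos[k, ] <- xyz[inn, ]
  }

  if (anyDuplicated(paste(chain, resno)))
    stop("duplicate residue numbers within a chain ",
         "(insertion codes are not supported)")

  cp <- matrix(NA_real_, n, 3L)
  for (k in seq_len(n - 1L)) {
    if (chain[k] != chain[k + 1L]) next
    cp[k, ] <- if (!anyNA(Cpos[k, ]) && !anyNA(Npos[k + 1L, ]))
      (Cpos[k, ] + Npos[k + 1L, ]) / 2
    else
      (ca[k, ] + ca[k + 1L, ]) / 2
  }

  if (!is.null(peptideChain)) {
    pc <- as.character(peptideChain)
    if (nchar(pc) == 1L && pc %in% chain) {
      chain[chain == pc] <- PEPTIDE_CHAIN
    } else {
      hit <- vapply(unique(chain), function(ch)
        paste(aa[chain == ch], collapse = "") == pc, logical(1L))
      if (!any(hit))
        stop(sprintf("no chain matches peptide selector '%s'", pc))
      chain[chain == unique(chain)[which(hit)[1L]]] <- PEPTIDE_CHAIN
    }
  }

  new("CGComplex", chain = chain, resno = resno, aa = aa,
      ca = ca, cb = cb, sc = sc, cp = cp)
}
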