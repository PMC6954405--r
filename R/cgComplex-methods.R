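#' Construct a coarse-grained complex
#'
#' Low-level constructor for [CGComplex-class]. Most users will obtain
#' complexes from [coarseGrain()], [buildPeptide()] or
#' [makeToyComplex()] instead.
#'
#' @param chain character per-residue chain labels (\code{"PEP"} marks
#'   the peptide chain).
#' @param resno integer per-residue numbers (unique within a chain).
#' @param aa character one-letter amino-acid codes.
#' @param ca,sc numeric \code{n x 3} coordinate matrices (Angstrom).
#' @param cb,cp like \code{ca} but rows may be \code{NA} (glycine CB,
#'   chain-terminal CP). Default to all-\code{NA}.
#' @return a validated [CGComplex-class].
#' @examples
#' pep <- buildPeptide("HAGPIA", seed = 1)
#' peptideLength(pep)
#' @export
CGComplex <- function(chain, resno, aa, ca, cb = NULL, sc = NULL,
                      cp = NULL) {
  n <- length(chain)
  if (is.null(cb)) cb <- matrix(NA_real_, n, 3L)
  if (is.null(cp)) cp <- matrix(NA_real_, n, 3L)
  if (is.null(sc)) sc <- ca
  new("CGComplex", chain = as.character(chain), resno = as.integer(resno),
      aa = toupper(as.character(aa)), ca = unname(ca), cb = unname(cb),
      sc = unname(sc), cp = unname(cp))
}

#' Accessors for coarse-grained complexes
#'
#' @param x a [CGComplex-class].
#' @param chain optional chain label to restrict to.
#' @param ... unused.
#' @param i integer or logical residue index.
#' @param j,drop ignored.
#' @name CGComplex-accessors
NULL

.chainSel <- function(x, chain) {
  if (is.null(chain)) rep(TRUE, length(x@chain)) else x@chain == chain
}

#' @rdname CGComplex-accessors
#' @export
setMethod("caCoords", "CGComplex", function(x, chain = NULL, ...)
  x@ca[.chainSel(x, chain), , drop = FALSE])

#' @rdname CGComplex-accessors
#' @export
setMethod("cbCoords", "CGComplex", function(x, chain = NULL, ...)
  x@cb[.chainSel(x, chain), , drop = FALSE])

#' @rdname CGComplex-accessors
#' @export
setMethod("scCoords", "CGComplex", function(x, chain = NULL, ...)
  x@sc[.chainSel(x, chain), , drop = FALSE])

#' @rdname CGComplex-accessors
#' @export
setMethod("cpCoords", "CGComplex", function(x, chain = NULL, ...)
  x@cp[.chainSel(x, chain), , drop = FALSE])

#' @rdname CGComplex-accessors
#' @export
setMethod("chainIds", "CGComplex", function(x) unique(x@chain))

#' @rdname CGComplex-accessors
#' @export
setMethod("length", "CGComplex", function(x) length(x@chain))

#' @rdname CGComplex-accessors
#' @export
setMethod("[", "CGComplex", function(x, i, j, ..., drop = FALSE) {
  new("CGComplex", chain = x@chain[i], resno = x@resno[i], aa = x@aa[i],
      ca = x@ca[i, , drop = FALSE], cb = x@cb[i, , drop = FALSE],
      sc = x@sc[i, , drop = FALSE], cp = x@cp[i, , drop = FALSE])
})

#' @rdname CGComplex-accessors
#' @export
setMethod("receptor", "CGComplex",
          function(x) x[x@chain != PEPTIDE_CHAIN])

#' @rdname CGComplex-accessors
#' @export
setMethod("peptide", "CGComplex",
          function(x) {
            if (!hasPeptide(x)) stop("complex has no peptide chain")
            x[x@chain == PEPTIDE_CHAIN]
          })

#' @rdname CGComplex-accessors
#' @export
setMethod("hasPeptide", "CGComplex",
          function(x) any(x@chain == PEPTIDE_CHAIN))

#' @rdname CGComplex-accessors
#' @export
setMethod("peptideLength", "CGComplex",
          function(x) sum(x@chain == PEPTIDE_CHAIN))

#' @rdname CGComplex-accessors
#' @export
setMethod("aaSequence", "CGComplex", function(x, chain = NULL, ...)
  paste(x@aa[.chainSel(x, chain)], collapse = ""))

#' @rdname CGComplex-accessors
#' @export
setMethod("residueTable", "CGComplex", function(x)
  data.frame(chain = x@chain, resno = x@resno, aa = x@aa,
             stringsAsFactors = FALSE))

setMethod("show", "CGComplex", function(object) {
  rec <- setdiff(unique(object@chain), PEPTIDE_CHAIN)
  cat(sprintf("CGComplex: %d residues\n", length(object)))
  for (ch in rec)
    cat(sprintf("  receptor chain %s: %d residues\n", ch,
                sum(object@chain == ch)))
  if (hasPeptide(object))
    cat(sprintf("  peptide (%s): %s\n", PEPTIDE_CHAIN,
                aaSequence(object, PEPTIDE_CHAIN)))
  invisible(NULL)
})

#' Combine receptor chains and a peptide chain into one complex
#'
#' @param receptor a [CGComplex-class] holding receptor chains only.
#' @param peptide a [CGComplex-class] holding the peptide chain (chain
#'   label is forced to \code{"PEP"}).
#' @return a [CGComplex-class] with the receptor chains followed by the
#'   peptide chain.
#' @export
bindPeptide <- function(receptor, peptide) {
  stopifnot(is(receptor, "CGComplex"), is(peptide, "CGComplex"))
  if (hasPeptide(receptor))
    stop("'receptor' already contains a peptide chain")
  new("CGComplex",
      chain = c(receptor@chain, rep(PEPTIDE_CHAIN, length(peptide))),
      resno = c(receptor@resno, peptide@resno),
      aa = c(receptor@aa, peptide@aa),
      ca = rbind(receptor@ca, peptide@ca),
      cb = rbind(receptor@cb, peptide@cb),
      sc = rbind(receptor@sc, peptide@sc),
      cp = rbind(receptor@cp, peptide@cp))
}

## Index of a residue given (resno, chain); error naming the residue if
## absent.
.residueIndex <- function(x, resno, chain) {
  i <- which(x@chain == chain & x@resno == resno)
  if (length(i) != 1L)
    stop(sprintf("residue %d of chain '%s' not found in complex",
                 resno, chain))
  i
}
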