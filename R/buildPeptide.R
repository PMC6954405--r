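## Random self-avoiding peptide chain generation in the CG representation.

## Approximate distance (Angstrom) from CA to the side-chain heavy-atom
## center of mass, per residue type. Glycine has no side chain (SC = CA).
SC_DISTANCE <- c(A = 1.53, C = 2.07, D = 2.48, E = 3.10, F = 3.40,
                 G = 0.00, H = 3.13, I = 2.30, K = 3.50, L = 2.60,
                 M = 2.95, N = 2.47, P = 1.87, Q = 3.09, R = 4.10,
                 S = 1.90, T = 1.93, V = 1.97, W = 3.86, Y = 3.80)

CA_BOND <- 3.8          # virtual CA-CA bond length, Angstrom
ANGLE_RANGE <- c(75, 150)  # allowed pseudo-bond angle range, degrees
CB_DISTANCE <- 1.53

## Secondary-structure sampling windows for the pseudo-angle theta and
## pseudo-dihedral phi (degrees): helix near (91, 52), strand extended.
SS_WINDOWS <- list(H = list(theta = c(87, 95), phi = c(42, 62)),
                   E = list(theta = c(115, 135), phi = c(170, 230)),
                   C = list(theta = ANGLE_RANGE, phi = c(0, 360)))

## Place a point at bond length r from p3, bond angle theta (deg) at p3
## and dihedral phi (deg) over p1-p2-p3-X (standard internal-coordinate
## chain extension).
.placeNext <- function(p1, p2, p3, r, thetaDeg, phiDeg) {
  th <- thetaDeg * pi / 180
  ph <- phiDeg * pi / 180
  bc <- .unit(p3 - p2)
  n <- .cross(p2 - p1, bc)
  if (sqrt(sum(n * n)) < 1e-8) {
    ref <- if (abs(bc[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    n <- .cross(ref, bc)
  }
  n <- .unit(n)
  m <- .cross(n, bc)
  d <- r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  p3 + d[1L] * bc + d[2L] * m + d[3L] * n
}

## Direction from CA towards the side chain: away from the mean of the
## bonds to the flanking residues (terminal residues: any fixed
## perpendicular to the single bond).
.sideDirection <- function(ca, i) {
  n <- nrow(ca)
  if (i > 1L && i < n) {
    v1 <- .unit(ca[i - 1L, ] - ca[i, ])
    v2 <- .unit(ca[i + 1L, ] - ca[i, ])
    u <- -(v1 + v2)
    if (sqrt(sum(u * u)) < 1e-6) {
      u <- .cross(v1, c(0, 0, 1))
      if (sqrt(sum(u * u)) < 1e-6) u <- .cross(v1, c(1, 0, 0))
    }
  } else {
    j <- if (i == 1L) 2L else n - 1L
    v <- .unit(ca[j, ] - ca[i, ])
    u <- .cross(v, c(0, 0, 1))
    if (sqrt(sum(u * u)) < 1e-6) u <- .cross(v, c(1, 0, 0))
  }
  .unit(u)
}

## Attach CB, SC and CP pseudo-atoms to a CA trace. Used by the builder
## and by moves that rebuild derived positions.
.dressCaTrace <- function(ca, aa, resno,
                          chain = rep(PEPTIDE_CHAIN, nrow(ca))) {
  n <- nrow(ca)
  cb <- sc <- cp <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    u <- .sideDirection(ca, i)
    if (aa[i] != "G") cb[i, ] <- ca[i, ] + CB_DISTANCE * u
    sc[i, ] <- ca[i, ] + SC_DISTANCE[[aa[i]]] * u
  }
  if (n > 1L)
    cp[seq_len(n - 1L), ] <- (ca[-n, , drop = FALSE] +
                                ca[-1L, , drop = FALSE]) / 2
  new("CGComplex", chain = chain, resno = as.integer(resno), aa = aa,
      ca = ca, cb = cb, sc = sc, cp = cp)
}

#' Build a random coarse-grained peptide from sequence
#'
#' Generates a self-avoiding CA trace with virtual bond lengths of 3.8
#' Angstrom and pseudo-bond angles restricted to \[75, 150\] degrees,
#' then places CB and SC pseudo-atoms along a per-residue-type offset in
#' the local backbone frame and CP pseudo-atoms at CA-CA midpoints. With
#' a secondary-structure string the pseudo-angles/dihedrals are drawn
#' from helix (\code{H}) or extended (\code{E}) windows instead of the
#' full coil range.
#'
#' The result is deterministic for a fixed \code{seed}.
#'
#' @param sequence one-letter amino-acid string, length >= 3.
#' @param ss optional per-residue secondary-structure string over
#'   \code{H}, \code{E}, \code{C}; same length as \code{sequence}.
#' @param seed integer RNG seed.
#' @return a [CGComplex-class] holding the single peptide chain
#'   (chain label \code{"PEP"}, residues numbered from 1).
#' @examples
#' pep <- buildPeptide("HAGPIA", seed = 1)
#' range(sqrt(rowSums(diff(caCoords(pep))^2)))  # all bonds 3.8 A
#' @export
buildPeptide <- function(sequence, ss = NULL, seed = 1L) {
  aa <- strsplit(toupper(sequence), "")[[1L]]
  n <- length(aa)
  if (n < 3L) stop("peptide sequence must have at least 3 residues")
  bad <- which(!(aa %in% AA1))
  if (length(bad))
    stop(sprintf("invalid amino-acid letter(s) at position(s): %s",
                 paste(bad, collapse = ", ")))
  if (!is.null(ss)) {
    ssv <- strsplit(toupper(ss), "")[[1L]]
    if (length(ssv) != n)
      stop("'ss' must have the same length as 'sequence'")
    if (!all(ssv %in% c("H", "E", "C")))
      stop("'ss' letters must be among H, E, C")
  } else ssv <- rep("C", n)

  .withSeed(seed, .buildPeptideInternal(aa, ssv))
}

## Grow and dress a chain until the result is free of internal clashes
## (the CA trace is self-avoiding by construction; side-chain sites of
## non-adjacent residues must also clear the soft-core radius).
.buildPeptideInternal <- function(aa, ssv, maxTries = 100L) {
  n <- length(aa)
  for (t in seq_len(maxTries)) {
    pep <- .dressCaTrace(.growCaTrace(n, ssv), aa, seq_len(n))
    if (excludedVolume(pep) == 0) return(pep)
  }
  stop("failed to build a clash-free peptide conformation")
}

.growCaTrace <- function(n, ssv, minSep = 3.6, maxRestart = 200L) {
  for (attempt in seq_len(maxRestart)) {
    ca <- matrix(NA_real_, n, 3L)
    ca[1L, ] <- c(0, 0, 0)
    ca[2L, ] <- c(CA_BOND, 0, 0)
    ok <- TRUE
    for (i in 3:n) {
      win <- SS_WINDOWS[[ssv[i - 1L]]]
      placed <- FALSE
      for (try in seq_len(200L)) {
        theta <- stats::runif(1L, win$theta[1L], win$theta[2L])
        phi <- stats::runif(1L, win$phi[1L], win$phi[2L])
        p1 <- if (i == 3L) ca[1L, ] + c(0, 1, 0) else ca[i - 3L, ]
        pos <- .placeNext(p1, ca[i - 2L, ], ca[i - 1L, ], CA_BOND,
                          theta, phi)
        prev <- ca[seq_len(i - 2L), , drop = FALSE]
        if (all(rowSums(sweep(prev, 2L, pos)^2) >= minSep^2)) {
          ca[i, ] <- pos
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(ca)
  }
  stop("failed to grow a self-avoiding peptide chain")
}
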