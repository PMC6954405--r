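# Shared fixtures: procedurally written all-atom PDB files and small
# hand-built CG complexes.

# Minimal all-atom tripeptide (ALA-GLY-SER) with idealized coordinates:
# residues along x at 3.8 A spacing, full backbone, CB/OG side chains.
aaAtomLine <- function(serial, name, resid, chain, resno, x, y, z,
                       occ = 1, alt = " ", type = "ATOM  ") {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          type, serial, name, alt, resid, chain, resno, x, y, z,
          occ, 0)
}

aaFixtureLines <- function() {
  fmt <- aaAtomLine
  lines <- character(0)
  serial <- 0
  add <- function(...) {
    serial <<- serial + 1
    lines <<- c(lines, fmt(serial, ...))
  }
  res <- list(list("ALA", 1), list("GLY", 2), list("SER", 3))
  for (r in res) {
    x0 <- 3.8 * (r[[2]] - 1)
    add("N", r[[1]], "A", r[[2]], x0 - 0.9, 0.8, 0.0)
    add("CA", r[[1]], "A", r[[2]], x0, 0.0, 0.0)
    add("C", r[[1]], "A", r[[2]], x0 + 1.2, 0.6, 0.0)
    add("O", r[[1]], "A", r[[2]], x0 + 1.2, 1.8, 0.0)
    if (r[[1]] != "GLY")
      add("CB", r[[1]], "A", r[[2]], x0, -1.0, 1.2)
    if (r[[1]] == "SER")
      add("OG", r[[1]], "A", r[[2]], x0, -2.0, 2.2)
  }
  c(lines, "END")
}

writeAAFixture <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(aaFixtureLines(), path)
  path
}

# A complex with receptor residues at prescribed SC positions and a
# peptide with prescribed SC positions (CA placed at the SC sites;
# alanine everywhere). For geometric unit tests only.
pointComplex <- function(recSc, pepSc) {
  recSc <- rbind(recSc)
  pepSc <- rbind(pepSc)
  nR <- nrow(recSc)
  nP <- nrow(pepSc)
  stopifnot(nP >= 3)
  CGComplex(chain = c(rep("R", nR), rep("PEP", nP)),
            resno = c(seq_len(nR), seq_len(nP)),
            aa = rep("A", nR + nP),
            ca = rbind(recSc, pepSc), sc = rbind(recSc, pepSc))
}

smallToy <- function(seed = 1) {
  makeToyComplex(toySystemSpec(receptorSize = 30, peptideLength = 5,
                               nPlantedContacts = 3, seed = seed))
}

# Trajectory with prescribed restraint distances and interaction
# energies, built on a toy reference (coordinates repeated; only the
# bookkeeping varies).
bookkeepingTrajectory <- function(reference, rdist, inter,
                                  restraints) {
  m <- length(inter)
  models <- replicate(m, reference, simplify = FALSE)
  en <- data.frame(model = seq_len(m), replica = 1L, sweep = seq_len(m),
                   interaction = inter, intraPeptide = 0,
                   excludedVolume = 0, restraint = 0, total = inter)
  CGPepDock:::.trajectoryFromModels(models, en, rdist, restraints)
}
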