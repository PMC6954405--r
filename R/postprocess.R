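## Pipeline stages after the docking simulation: contact-criterion
## filtering, interaction-energy filtering, k-medoids clustering on the
## pairwise peptide-RMSD matrix, and top-model selection.

#' Filter trajectory models by the contact criterion
#'
#' A model satisfies a restraint when its recorded SC-SC distance is at
#' most the cutoff \code{d0} (the zero-energy region of the restraint
#' term). Models that do not satisfy the user-provided contact
#' criterion are removed from the trajectory before clustering and
#' scoring. With multiple restraints, mode \code{"all"} keeps models
#' satisfying every restraint and mode \code{"any"} at least one;
#' \code{"off"} (or an empty restraint set) returns the input
#' unchanged.
#'
#' @param trajectory a [Trajectory-class] with recorded restraint
#'   distances.
#' @param restraints the [RestraintSet-class] to filter on (default:
#'   the set recorded in the trajectory).
#' @param mode one of \code{"all"}, \code{"any"}, \code{"off"}.
#' @return the filtered [Trajectory-class] subset.
#' @export
filterByContact <- function(trajectory,
                            restraints = restraintSet(trajectory),
                            mode = c("all", "any", "off")) {
  mode <- match.arg(mode)
  if (mode == "off" || length(restraints) == 0L) return(trajectory)
  d0 <- vapply(restraints@restraints, function(r) r@d0, numeric(1L))
  D <- restraintDistances(trajectory)
  if (ncol(D) != length(restraints))
    stop("trajectory does not record distances for this restraint set")
  sat <- sweep(D, 2L, d0, "<=")
  keep <- if (mode == "all") rowSums(!sat) == 0L else rowSums(sat) > 0L
  if (!any(keep))
    warning("no model satisfies the contact criterion; ",
            "returning an empty trajectory")
  trajectory[which(keep)]
}

#' Filter trajectory models by interaction energy
#'
#' Keeps the \code{nKeep} models with the lowest receptor-peptide
#' interaction energy (default 1000, matching the pipeline default of
#' selecting 1000 low-energy models from 10000 conformations). Ties are
#' broken by model index, ascending. If fewer models are available, all
#' are kept with a warning.
#'
#' @param trajectory a [Trajectory-class].
#' @param nKeep number of models to retain.
#' @return the filtered [Trajectory-class] subset (original model
#'   order).
#' @export
filterByEnergy <- function(trajectory, nKeep = 1000L) {
  m <- nModels(trajectory)
  if (m < nKeep) {
    warning(sprintf("only %d models available; keeping all", m))
    nKeep <- m
  }
  ord <- order(trajectory@energies$interaction,
               seq_len(m))[seq_len(nKeep)]
  trajectory[sort(ord)]
}

## Peptide CA coordinates of every model after superposing each model's
## receptor CAs onto the first model's receptor: rows = models, columns
## = flattened peptide coordinates.
.alignedPeptideCoords <- function(trajectory) {
  tpl <- trajectory@template
  recIdx <- which(tpl@chain != PEPTIDE_CHAIN)
  pepIdx <- which(tpl@chain == PEPTIDE_CHAIN)
  m <- nModels(trajectory)
  ref <- trajectory@ca[recIdx, , 1L]
  out <- matrix(0, m, length(pepIdx) * 3L)
  for (i in seq_len(m)) {
    fit <- superpose(trajectory@ca[recIdx, , i], ref)
    pep <- trajectory@ca[pepIdx, , i] %*% fit$rotation +
      rep(fit$translation, each = length(pepIdx))
    out[i, ] <- as.vector(pep)
  }
  out
}

## Pairwise peptide-RMSD matrix between aligned models.
.peptideRmsdMatrix <- function(trajectory) {
  flat <- .alignedPeptideCoords(trajectory)
  npep <- ncol(flat) / 3L
  as.matrix(stats::dist(flat)) / sqrt(npep)
}

## Deterministic k-medoids: farthest-point seeding from a seeded random
## start, then alternating assignment / medoid update. Ties broken by
## lowest index. Small instances are solved exactly by enumerating all
## medoid combinations.
.kmedoids <- function(D, k, seed = 1L) {
  n <- nrow(D)
  stopifnot(k >= 1L, k <= n)
  if (choose(n, k) <= 2000) {
    combos <- utils::combn(n, k)
    cost <- apply(combos, 2L, function(med)
      sum(apply(D[, med, drop = FALSE], 1L, min)))
    med <- combos[, which.min(cost)]
    assign <- apply(D[, med, drop = FALSE], 1L, which.min)
    assign[med] <- seq_len(k)
    return(list(medoids = as.integer(med),
                assignment = as.integer(assign)))
  }
  med <- integer(k)
  med[1L] <- .withSeed(seed, sample.int(n, 1L))
  if (k > 1L) {
    for (j in 2:k) {
      dmin <- apply(D[, med[seq_len(j - 1L)], drop = FALSE], 1L, min)
      dmin[med[seq_len(j - 1L)]] <- -1
      med[j] <- which.max(dmin)
    }
  }
  assign <- NULL
  for (iter in seq_len(100L)) {
    assign <- apply(D[, med, drop = FALSE], 1L, which.min)
    assign[med] <- seq_len(k)
    newMed <- vapply(seq_len(k), function(cl) {
      members <- which(assign == cl)
      members[which.min(colSums(D[members, members, drop = FALSE]))]
    }, integer(1L))
    if (identical(newMed, med)) break
    med <- newMed
  }
  list(medoids = med, assignment = as.integer(assign))
}

## Density score of a cluster: size / mean intra-cluster pairwise
## distance; size for singletons or fully degenerate clusters.
.clusterDensity <- function(D, members) {
  sz <- length(members)
  if (sz == 1L) return(sz)
  sub <- D[members, members]
  meanD <- mean(sub[upper.tri(sub)])
  if (meanD == 0) sz else sz / meanD
}

#' Cluster filtered models and select the final representatives
#'
#' k-medoids clustering (deterministic farthest-point seeding) on the
#' pairwise peptide-RMSD matrix of the given models, computed over
#' peptide CA atoms after superposing every model's receptor CAs onto
#' the first model's receptor. Each cluster is scored by density
#' (cluster size divided by the mean intra-cluster pairwise
#' peptide-RMSD; the size itself for singletons), and the cluster
#' medoids, ordered by decreasing density, are the final models
#' (default 10).
#'
#' @param trajectory a (filtered) [Trajectory-class].
#' @param k number of clusters / final models (default 10; reduced with
#'   a warning when fewer models are available).
#' @param seed integer RNG seed for the clustering initialization.
#' @return a [ClusterReport-class].
#' @export
clusterModels <- function(trajectory, k = 10L, seed = 1L) {
  m <- nModels(trajectory)
  if (m < k) {
    warning(sprintf("only %d models to cluster; reducing k from %d",
                    m, k))
    k <- m
  }
  D <- .peptideRmsdMatrix(trajectory)
  km <- .kmedoids(D, k, seed)
  dens <- vapply(seq_len(k), function(cl)
    .clusterDensity(D, which(km$assignment == cl)), numeric(1L))
  ord <- order(-dens, seq_len(k))
  new("ClusterReport", assignment = km$assignment,
      medoids = km$medoids, density = dens,
      finalModels = km$medoids[ord], trajectory = trajectory,
      provenance = list(input = m, clusters = k))
}

#' Run the post-simulation pipeline
#'
#' Applies the full post-processing protocol to a docking trajectory:
#' contact-criterion filtering (models violating a restraint cutoff are
#' excluded), interaction-energy filtering (default: 1000 lowest-energy
#' models), then clustering and scoring (default: 10 final models). If
#' no model satisfies the contact criterion, the pipeline falls back,
#' with a loud warning, to the models with the smallest total restraint
#' energy, so that hard targets with poorly accessible binding sites
#' still produce output.
#'
#' @param trajectory a [Trajectory-class].
#' @param restraints the [RestraintSet-class] used for contact
#'   filtering (default: the trajectory's own).
#' @param nKeepEnergy models retained by the energy filter (default
#'   1000).
#' @param contactMode \code{"all"}, \code{"any"} or \code{"off"}.
#' @param k number of clusters / final models (default 10).
#' @param seed integer RNG seed for clustering.
#' @return a [ClusterReport-class]; its provenance records the model
#'   counts surviving each stage.
#' @examples
#' toy <- makeToyComplex(toySystemSpec(seed = 1))
#' traj <- syntheticTrajectory(toy$bound, nModels = 200, seed = 2)
#' rep <- runPipeline(traj, nKeepEnergy = 50, k = 5)
#' finalModels(rep)
#' @export
runPipeline <- function(trajectory,
                        restraints = restraintSet(trajectory),
                        nKeepEnergy = 1000L,
                        contactMode = c("all", "any", "off"),
                        k = 10L, seed = 1L) {
  contactMode <- match.arg(contactMode)
  nInput <- nModels(trajectory)
  contacted <- suppressWarnings(
    filterByContact(trajectory, restraints, contactMode))
  fallback <- FALSE
  if (nModels(contacted) == 0L) {
    warning("contact filter removed every model; falling back to the ",
            nKeepEnergy, " models with the smallest restraint energy")
    fallback <- TRUE
    d0 <- vapply(restraints@restraints, function(r) r@d0, numeric(1L))
    s <- vapply(restraints@restraints, function(r) r@s, numeric(1L))
    viol <- sweep(restraintDistances(trajectory), 2L, d0)
    viol[viol < 0] <- 0
    rEnergy <- as.vector(viol %*% s)
    ord <- order(rEnergy, seq_len(nInput))
    contacted <- trajectory[sort(ord[seq_len(min(nKeepEnergy, nInput))])]
  }
  nContact <- nModels(contacted)
  lowE <- suppressWarnings(filterByEnergy(contacted, nKeepEnergy))
  nEnergy <- nModels(lowE)
  report <- clusterModels(lowE, k, seed)
  report@provenance <- list(input = nInput, contactFilter = nContact,
                            energyFilter = nEnergy,
                            finalModels = length(report@finalModels),
                            contactFallback = fallback)
  report
}
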