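#' Accessors for docking trajectories
#'
#' @param x a [Trajectory-class].
#' @param i model index (integer or logical).
#' @param ... unused.
#' @name Trajectory-accessors
NULL

#' @rdname Trajectory-accessors
#' @export
setMethod("nModels", "Trajectory", function(x) nrow(x@energies))

#' @rdname Trajectory-accessors
#' @export
setMethod("getModel", "Trajectory", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= nModels(x))
  tpl <- x@template
  new("CGComplex", chain = tpl@chain, resno = tpl@resno, aa = tpl@aa,
      ca = x@ca[, , i], cb = x@cb[, , i], sc = x@sc[, , i],
      cp = x@cp[, , i])
})

#' @rdname Trajectory-accessors
#' @export
setMethod("energyTable", "Trajectory", function(x) x@energies)

#' @rdname Trajectory-accessors
#' @export
setMethod("restraintDistances", "Trajectory",
          function(x, ...) x@restraintDistances)

#' @rdname Trajectory-accessors
#' @export
setMethod("restraintSet", "Trajectory", function(x) x@restraints)

#' @rdname Trajectory-accessors
#' @param j,drop ignored.
#' @export
setMethod("[", "Trajectory", function(x, i, j, ..., drop = FALSE) {
  if (is.logical(i)) i <- which(i)
  i <- as.integer(i)
  en <- x@energies[i, , drop = FALSE]
  rownames(en) <- NULL
  new("Trajectory", template = x@template,
      ca = x@ca[, , i, drop = FALSE], cb = x@cb[, , i, drop = FALSE],
      sc = x@sc[, , i, drop = FALSE], cp = x@cp[, , i, drop = FALSE],
      energies = en,
      restraintDistances = x@restraintDistances[i, , drop = FALSE],
      restraints = x@restraints, modelIndex = x@modelIndex[i])
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d models, %d residues (%d peptide)\n",
              nModels(object), length(object@template),
              peptideLength(object@template)))
  if (length(object@restraints) > 0L)
    cat(sprintf("  %d contact restraint(s) recorded\n",
                length(object@restraints)))
  if (nModels(object) > 0L)
    cat(sprintf("  interaction energy range: [%.2f, %.2f]\n",
                min(object@energies$interaction),
                max(object@energies$interaction)))
  invisible(NULL)
})

#' Accessors for cluster reports
#'
#' @param x a [ClusterReport-class].
#' @name ClusterReport-accessors
NULL

#' @rdname ClusterReport-accessors
#' @export
setMethod("finalModels", "ClusterReport", function(x) x@finalModels)

#' @rdname ClusterReport-accessors
#' @export
setMethod("clusterTable", "ClusterReport", function(x) {
  k <- length(x@medoids)
  data.frame(cluster = seq_len(k),
             size = as.integer(tabulate(x@assignment, k)),
             density = x@density, medoid = x@medoids)
})

setMethod("show", "ClusterReport", function(object) {
  cat(sprintf("ClusterReport: %d clusters over %d models\n",
              length(object@medoids), length(object@assignment)))
  print(clusterTable(object))
  if (length(object@provenance))
    cat("  pipeline counts:",
        paste(names(object@provenance), unlist(object@provenance),
              sep = "=", collapse = ", "), "\n")
  invisible(NULL)
})
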