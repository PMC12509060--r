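#' @include AllClasses.R
NULL

#' Accessors for gxenet classes
#'
#' `moduleAssignments()` returns the named gene -> module-id vector of a
#' [ModuleSet-class]; `eigengenes()` its sample x module eigengene matrix;
#' `libraryType()` the library-type tag of a ModuleSet or
#' [CausalGraph-class]; `graphEdges()` the edge table of a CausalGraph;
#' `cliqueTable()` the per-clique summary of a [CliqueReport-class].
#'
#' @param object a gxenet object.
#' @return See the individual descriptions above.
#' @name accessors
#' @aliases moduleAssignments eigengenes libraryType graphEdges cliqueTable
#' @examples
#' showMethods("moduleAssignments")
NULL

#' @rdname accessors
#' @export
setGeneric("moduleAssignments",
           function(object) standardGeneric("moduleAssignments"))

#' @rdname accessors
#' @export
setGeneric("eigengenes", function(object) standardGeneric("eigengenes"))

#' @rdname accessors
#' @export
setGeneric("libraryType", function(object) standardGeneric("libraryType"))

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))

#' @rdname accessors
#' @export
setGeneric("cliqueTable", function(object) standardGeneric("cliqueTable"))

#' @rdname accessors
#' @export
setMethod("moduleAssignments", "ModuleSet", function(object) object@assignment)

#' @rdname accessors
#' @export
setMethod("eigengenes", "ModuleSet", function(object) object@eigengenes)

#' @rdname accessors
#' @export
setMethod("libraryType", "ModuleSet", function(object) object@libraryType)

#' @rdname accessors
#' @export
setMethod("libraryType", "CausalGraph", function(object) object@libraryType)

#' @rdname accessors
#' @export
setMethod("graphEdges", "CausalGraph", function(object) object@edges)

#' @rdname accessors
#' @export
setMethod("cliqueTable", "CliqueReport", function(object) object@cliques)

setMethod("show", "ModuleSet", function(object) {
  k <- sum(tabulate(object@assignment) > 0)
  n0 <- sum(object@assignment == 0)
  cat("ModuleSet (", object@libraryType, ", preset ", object@preset, ")\n",
      sep = "")
  cat("  ", length(object@assignment), " genes in ",
      length(unique(object@assignment[object@assignment > 0])),
      " modules; ", n0, " unassigned\n", sep = "")
  sizes <- table(object@assignment[object@assignment > 0])
  if (length(sizes))
    cat("  module sizes: ",
        paste(utils::head(as.integer(sizes), 10), collapse = ", "),
        if (length(sizes) > 10) ", ..." else "", "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "CliqueReport", function(object) {
  cat("CliqueReport: ", nrow(object@cliques), " cliques from ",
      nrow(object@edges), " significant module overlaps (P < ",
      format(object@pCutoff), ", universe ", object@universeSize,
      " genes)\n", sep = "")
  if (nrow(object@cliques))
    print(table(object@cliques$pattern))
  invisible(NULL)
})

setMethod("show", "CausalGraph", function(object) {
  cat("CausalGraph for module ", object@moduleId, " (observational ",
      object@libraryType, ")\n", sep = "")
  cat("  ", length(object@nodes), " connected nodes, ", nrow(object@edges),
      " retained edges (threshold ", signif(object@threshold, 3), ", ",
      object@nSubsamples, " subsamples)\n", sep = "")
  invisible(NULL)
})

setMethod("show", "GroundTruth", function(object) {
  ma <- object@moduleAssignment
  cat("GroundTruth: ", length(ma), " genes, ",
      length(unique(ma[ma > 0])), " planted modules, ",
      nrow(object@dagEdges), " dag edges, ",
      sum(object@aseMode != "none"), " allelic-effect genes\n", sep = "")
  invisible(NULL)
})
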