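# Plain-text input/output: TSV tables, GMT gene sets, ground-truth JSON.

#' Read a count matrix and design table from TSV files
#'
#' @param countsFile TSV with gene ids in the first column and one column
#'   per sample.
#' @param designFile TSV with columns `sample_id`, `genotype`, `treatment`.
#' @return A [GxEExperiment-class].
#' @export
readCountsTsv <- function(countsFile, designFile) {
  cts <- utils::read.delim(countsFile, row.names = 1, check.names = FALSE)
  design <- utils::read.delim(designFile, stringsAsFactors = FALSE)
  GxEExperiment(as.matrix(cts), design)
}

#' Write a GxEExperiment's counts and design as TSV
#'
#' @param x a [GxEExperiment-class].
#' @param countsFile,designFile output paths.
#' @return The file paths, invisibly.
#' @export
writeCountsTsv <- function(x, countsFile, designFile) {
  cts <- SummarizedExperiment::assay(x, "counts")
  utils::write.table(data.frame(gene = rownames(cts), cts,
                                check.names = FALSE),
                     countsFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cd <- SummarizedExperiment::colData(x)
  design <- data.frame(sample_id = rownames(cd),
                       genotype = cd$genotype, treatment = cd$treatment,
                       library_type = cd$libraryType)
  utils::write.table(design, designFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(countsFile, designFile))
}

#' Serialize a GroundTruth object to JSON
#'
#' @param truth a [GroundTruth-class].
#' @param file output path.
#' @return The file path, invisibly.
#' @export
writeGroundTruthJson <- function(truth, file) {
  obj <- list(moduleAssignment = as.list(truth@moduleAssignment),
              dagEdges = truth@dagEdges,
              meanEffects = truth@meanEffects,
              sigmaOverride = truth@sigmaOverride,
              traitLoadings = truth@traitLoadings,
              aseMode = as.list(truth@aseMode),
              aseEffect = as.list(truth@aseEffect))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read and write gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene ids.
#'
#' @param file path of the GMT file.
#' @return `readGmt`: named list of character vectors.
#' @export
readGmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1),
    USE.NAMES = FALSE)
  out
}

#' @rdname readGmt
#' @param sets named list of character vectors.
#' @param description optional per-set description column.
#' @export
writeGmt <- function(sets, file, description = names(sets)) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Write a ModuleSet's membership and eigengenes as TSV
#'
#' @param moduleSet a [ModuleSet-class].
#' @param membershipFile,eigengeneFile output paths (either may be NULL).
#' @return The file paths, invisibly.
#' @export
writeModuleSetTsv <- function(moduleSet, membershipFile = NULL,
                              eigengeneFile = NULL) {
  if (!is.null(membershipFile)) {
    a <- moduleAssignments(moduleSet)
    utils::write.table(
      data.frame(gene = names(a), module = a,
                 library_type = libraryType(moduleSet),
                 preset = moduleSet@preset),
      membershipFile, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(eigengeneFile)) {
    eg <- eigengenes(moduleSet)
    utils::write.table(
      data.frame(sample_id = rownames(eg), eg, check.names = FALSE),
      eigengeneFile, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(membershipFile, eigengeneFile))
}
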