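## Plain-text readers and writers: whitespace-delimited square matrices
## with a one-line atlas header, atlas and phenotype CSVs.

#' Write a square matrix as TSV
#'
#' N rows x N columns, tab-delimited, no row labels, preceded by a header
#' comment line \code{# atlas=<name> n=<N>}.
#'
#' @param m square numeric matrix.
#' @param file output path.
#' @param atlasName atlas identifier for the header.
#' @return invisibly, the file path.
#' @export
writeMatrixTSV <- function(m, file, atlasName = "atlas") {
  stopIfNot(is.matrix(m) && nrow(m) == ncol(m), "m must be square")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# atlas=%s n=%d", atlasName, nrow(m)), con)
  utils::write.table(m, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a square matrix written by \code{writeMatrixTSV}
#'
#' Tolerant of comma- as well as whitespace-delimited content; comment
#' lines starting with '#' are skipped.
#'
#' @param file input path.
#' @return numeric matrix.
#' @export
readMatrixTSV <- function(file) {
  first <- readLines(file, n = 20L)
  first <- first[!startsWith(trimws(first), "#")]
  sep <- if (length(first) && grepl(",", first[1])) "," else ""
  m <- as.matrix(utils::read.table(file, sep = sep, comment.char = "#",
                                   header = FALSE))
  dimnames(m) <- NULL
  stopIfNot(nrow(m) == ncol(m), "matrix in file is not square")
  m
}

#' Write a cohort to disk
#'
#' Writes \code{atlas.csv} (node_id,label,hemisphere,x,y,z,volume),
#' \code{phenotypes.csv} (one row per subject) and, per subject,
#' \code{<subject_id>_fn.tsv} and \code{<subject_id>_fa.tsv} matrices with
#' an atlas header line.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param dir output directory (created if missing).
#' @return invisibly, \code{dir}.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  atl <- atlas(cohort)
  utils::write.csv(as.data.frame(atl), file.path(dir, "atlas.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(phenotypes(cohort), file.path(dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  for (id in names(connectomes(cohort))) {
    rc <- connectomes(cohort)[[id]]
    writeMatrixTSV(rc@fn, file.path(dir, sprintf("%s_fn.tsv", id)), atl@name)
    writeMatrixTSV(rc@fa, file.path(dir, sprintf("%s_fa.tsv", id)), atl@name)
  }
  invisible(dir)
}

#' Read a cohort directory written by \code{writeCohort}
#'
#' @param dir directory containing atlas.csv, phenotypes.csv and the
#'   per-subject fn/fa matrices.
#' @return list with elements \code{atlas} (\linkS4class{NodeAtlas}),
#'   \code{phenotypes} (data.frame) and \code{connectomes} (named list of
#'   \linkS4class{RawConnectome}).
#' @export
readCohortDir <- function(dir) {
  adf <- utils::read.csv(file.path(dir, "atlas.csv"),
                         stringsAsFactors = FALSE)
  atl <- nodeAtlas(adf$label, adf$hemisphere,
                   as.matrix(adf[, c("x", "y", "z")]), adf$volume)
  phen <- utils::read.csv(file.path(dir, "phenotypes.csv"),
                          stringsAsFactors = FALSE)
  conns <- lapply(phen$subjectId, function(id) {
    fn <- readMatrixTSV(file.path(dir, sprintf("%s_fn.tsv", id)))
    fa <- readMatrixTSV(file.path(dir, sprintf("%s_fa.tsv", id)))
    new("RawConnectome", fn = fn, fa = fa, volumes = nodeVolumes(atl),
        atlas = atl)
  })
  names(conns) <- phen$subjectId
  list(atlas = atl, phenotypes = phen, connectomes = conns)
}
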