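## Tabular readers/writers. All formats are TAB-separated UTF-8 with a header
## row, except GMT which follows the headerless gene-set convention.

.readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, quote = "", comment.char = "",
             colClasses = "character")
}

.requireColumns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("format error in '", path, "': missing column(s) ",
         paste(miss, collapse = ", "))
}

#' Read a miRNA target prediction table
#'
#' Expects a TSV with header columns \code{mirna}, \code{gene}, \code{tool}.
#' Duplicate (mirna, gene, tool) triples are collapsed silently; their count
#' is recorded in the returned object and reported via \code{message()}.
#'
#' @param path path to the predictions TSV
#' @return a \linkS4class{TargetPredictions} object
#' @export
readPredictions <- function(path) {
  df <- .readTsv(path)
  .requireColumns(df, c("mirna", "gene", "tool"), path)
  df <- df[c("mirna", "gene", "tool")]
  TargetPredictions(df)
}

#' Construct a TargetPredictions object from a data.frame
#'
#' @param df data.frame with character columns mirna, gene, tool
#' @return a validated \linkS4class{TargetPredictions}
#' @export
TargetPredictions <- function(df) {
  df <- data.frame(lapply(df, as.character), stringsAsFactors = FALSE)
  dup <- duplicated(df)
  if (any(dup)) {
    message(sum(dup), " duplicate prediction triple(s) dropped")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  new("TargetPredictions", predictions = df,
      nDuplicatesDropped = sum(dup))
}

#' Write a target prediction table
#' @param object a \linkS4class{TargetPredictions}
#' @param path output TSV path
#' @export
writePredictions <- function(object, path) {
  write.table(object@predictions, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file into a pathway database
#'
#' Standard GMT: one pathway per line, fields name, description, then the
#' gene ids, TAB-separated, no header. The description field is kept as the
#' pathway's source label. Interactions start empty; attach them with
#' \code{\link{readInteractions}}.
#'
#' @param path path to the GMT file
#' @return a \linkS4class{PathwayDb}
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("format error in '", path, "': line ", bad[1],
         " has fewer than 3 fields")
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate pathway name in '", path, "': ",
         ids[duplicated(ids)][1])
  src <- vapply(fields, `[[`, "", 2L)
  gs <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(gs) <- ids
  new("PathwayDb", geneSets = gs, source = setNames(src, ids))
}

#' Write a pathway database's gene sets as GMT
#' @param db a \linkS4class{PathwayDb}
#' @param path output path
#' @export
writeGmt <- function(db, path) {
  src <- db@source
  if (!length(src)) src <- setNames(rep("", length(db@geneSets)),
                                    names(db@geneSets))
  lines <- vapply(names(db@geneSets), function(id)
    paste(c(id, src[[id]], db@geneSets[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Attach signed interactions to a pathway database
#'
#' Reads a TSV with columns \code{pathway_id}, \code{interaction_id},
#' \code{gene}, \code{role} where role is one of \code{promoter},
#' \code{inhibitor}, \code{output}. Every interaction gene must be a member
#' of its pathway's gene set and every interaction must have at least one
#' promoter or inhibitor.
#'
#' @param path path to the interactions TSV
#' @param db the \linkS4class{PathwayDb} the interactions belong to
#' @return \code{db} with the interactions attached
#' @export
readInteractions <- function(path, db) {
  df <- .readTsv(path)
  .requireColumns(df, c("pathway_id", "interaction_id", "gene", "role"), path)
  df <- df[c("pathway_id", "interaction_id", "gene", "role")]
  badRole <- setdiff(unique(df$role), c("promoter", "inhibitor", "output"))
  if (length(badRole))
    stop("format error in '", path, "': unknown role token '", badRole[1], "'")
  badPid <- setdiff(unique(df$pathway_id), names(db@geneSets))
  if (length(badPid))
    stop("unknown pathway_id in '", path, "': ", badPid[1])
  for (pid in unique(df$pathway_id)) {
    out <- setdiff(df$gene[df$pathway_id == pid], db@geneSets[[pid]])
    if (length(out))
      stop("consistency error: gene '", out[1],
           "' of an interaction is not in pathway '", pid, "'")
  }
  rownames(df) <- NULL
  db@interactions <- df
  validObject(db)
  db
}

#' Write a pathway database's interactions
#' @param db a \linkS4class{PathwayDb}
#' @param path output TSV path
#' @export
writeInteractions <- function(db, path) {
  write.table(db@interactions, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix
#'
#' TSV with the feature id in the first column (genes or miRNAs) and one
#' column per sample. All cells must be finite numbers; feature ids must be
#' unique.
#'
#' @param path path to the expression TSV
#' @param scale free-text scale tag stored in the object metadata
#'   (e.g. "RMA-level")
#' @return a \code{SummarizedExperiment} with assay \code{exprs}
#' @export
readExpression <- function(path, scale = "unspecified") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE, quote = "")
  if (ncol(df) < 2L) stop("format error in '", path, "': no sample columns")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature id in '", path, "': ", ids[duplicated(ids)][1])
  m <- as.matrix(df[-1])
  if (!is.numeric(m) || any(!is.finite(m)))
    stop("format error in '", path, "': non-numeric or non-finite cell")
  rownames(m) <- ids
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = m), metadata = list(scale = scale))
}

#' Write an expression matrix (or any single-assay SummarizedExperiment)
#' @param se SummarizedExperiment or numeric matrix with dimnames
#' @param path output TSV path
#' @param idColumn header name of the feature-id column
#' @export
writeExpression <- function(se, path, idColumn = "feature") {
  m <- if (is.matrix(se)) se else SummarizedExperiment::assay(se)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- idColumn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample phenotype table
#'
#' TSV with columns \code{sample}, \code{group} and optionally \code{time}
#' (non-negative survival time in days) and \code{event} (0/1 or
#' TRUE/FALSE). If \code{time} is present \code{event} must be too.
#'
#' @param path path to the phenotype TSV
#' @return an \code{S4Vectors::DataFrame} with rownames = sample ids
#' @export
readPhenotypes <- function(path) {
  df <- .readTsv(path)
  .requireColumns(df, c("sample", "group"), path)
  if (anyDuplicated(df$sample))
    stop("duplicate sample id in '", path, "': ",
         df$sample[duplicated(df$sample)][1])
  out <- S4Vectors::DataFrame(sample = df$sample,
                              group = factor(df$group),
                              row.names = df$sample)
  if ("time" %in% names(df)) {
    if (!"event" %in% names(df))
      stop("format error in '", path, "': 'time' present without 'event'")
    tm <- suppressWarnings(as.numeric(df$time))
    if (any(is.na(tm)) || any(tm < 0))
      stop("format error in '", path, "': negative or non-numeric survival time")
    ev <- df$event %in% c("1", "TRUE", "true")
    if (!all(df$event %in% c("0", "1", "TRUE", "FALSE", "true", "false")))
      stop("format error in '", path, "': event must be 0/1 or TRUE/FALSE")
    out$time <- tm
    out$event <- ev
  }
  out
}

#' Write a phenotype table
#' @param phenotypes DataFrame as returned by \code{\link{readPhenotypes}}
#' @param path output TSV path
#' @export
writePhenotypes <- function(phenotypes, path) {
  df <- as.data.frame(phenotypes)
  df$group <- as.character(df$group)
  if ("event" %in% names(df)) df$event <- as.integer(df$event)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
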