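#' Read a GMT gene-set file
#'
#' MSigDB dialect: one set per tab-delimited line — set name, description,
#' then member genes. Duplicate members are deduplicated (count reported via
#' message); a line with fewer than 3 fields is an error naming the line.
#'
#' @param path file path.
#' @param name,source collection name and source tag; name defaults to the
#'   file name.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path, name = NULL, source = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(geneSets(list(), name = name %||% basename(path), source = source))
  }
  nDup <- 0L
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 fields")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    nDup <- nDup + (length(genes) - length(unique(genes)))
    sets[[f[1L]]] <- unique(genes)
  }
  if (nDup > 0L) message(nDup, " duplicate member(s) deduplicated")
  geneSets(sets, name = name %||% basename(path), source = source)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a gene-set collection as GMT
#'
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeGmt <- function(collection, path) {
  sets <- setMembers(collection)
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, collection@source, sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

.readTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE)
}

.requireColumns <- function(df, need, what) {
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
}

#' Read a tab-delimited expression matrix
#'
#' First column gene ids, remaining columns samples; every cell must be
#' numeric (an error names the offending row and column).
#'
#' @param path file path.
#' @return numeric matrix, genes x samples.
#' @export
readExpression <- function(path) {
  df <- .readTable(path)
  if (ncol(df) < 2L) stop("expression table needs gene ids plus samples")
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(m), nrow(m)))) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad))
      stop("non-numeric expression value at row ", genes[bad[1L, 1L]],
           ", column ", colnames(m)[bad[1L, 2L]])
    m <- matrix(as.numeric(m), nrow(m), dimnames = dimnames(m))
  }
  rownames(m) <- genes
  m
}

#' Read sample metadata
#'
#' Tab-delimited with header; requires \code{sample_id}, \code{subject_id},
#' \code{group}, \code{stimulation}, \code{gender}, \code{batch}. Group and
#' stimulation tokens are normalized case-insensitively; unknown tokens and
#' duplicate (subject, stimulation) pairs are errors.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
readMetadata <- function(path) {
  df <- .readTable(path)
  .requireColumns(df, c("sample_id", "subject_id", "group", "stimulation",
                        "gender", "batch"), "metadata")
  df$group <- toupper(df$group)
  df$stimulation <- toupper(df$stimulation)
  bad <- setdiff(unique(df$group), .VALID_GROUPS)
  if (length(bad)) stop("unknown group token(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$stimulation), .VALID_STIM)
  if (length(bad))
    stop("unknown stimulation token(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(paste(df$subject_id, df$stimulation)))
    stop("duplicate (subject, stimulation) pair in metadata")
  df
}

#' Read a long-format cytokine table
#'
#' Requires \code{subject_id}, \code{group}, \code{cytokine},
#' \code{condition}, \code{concentration} (pg/ml, non-negative numeric).
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
readCytokines <- function(path) {
  df <- .readTable(path)
  .requireColumns(df, c("subject_id", "group", "cytokine", "condition",
                        "concentration"), "cytokine table")
  df$group <- toupper(df$group)
  df$condition <- toupper(df$condition)
  bad <- setdiff(unique(df$condition), .VALID_STIM)
  if (length(bad))
    stop("unknown condition token(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(df$concentration) || any(!is.finite(df$concentration)) ||
      any(df$concentration < 0))
    stop("concentration must be non-negative numeric")
  df
}

#' Read a signature-to-category annotation map
#'
#' Tab-delimited, UTF-8, header required; columns \code{level},
#' \code{category}, \code{signature_name}.
#'
#' @param path file path.
#' @return an \linkS4class{AnnotationMap}.
#' @export
readAnnotation <- function(path) {
  df <- .readTable(path)
  .requireColumns(df, c("level", "category", "signature_name"),
                  "annotation map")
  annotationMap(data.frame(level = as.integer(df$level),
                           signature = df$signature_name,
                           category = df$category,
                           stringsAsFactors = FALSE))
}

#' Write an annotation map
#'
#' @param map an \linkS4class{AnnotationMap}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeAnnotation <- function(map, path) {
  a <- map@assignments
  out <- data.frame(level = a$level, category = a$category,
                    signature_name = a$signature)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a data frame as a tab-delimited table
#'
#' Full-precision values, header, no quoting or row names.
#'
#' @param df data.frame.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
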