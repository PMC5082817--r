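#' Construct a StimExperiment
#'
#' @param exprs numeric matrix of log2-scale expression, genes in rows,
#'   samples in columns; dimnames required.
#' @param sampleData data.frame (or DataFrame) with one row per column of
#'   \code{exprs}, carrying \code{subject_id}, \code{group}, \code{stimulation},
#'   \code{gender}, \code{batch}. Group and stimulation tokens are matched
#'   case-insensitively.
#' @return A \linkS4class{StimExperiment}.
#' @examples
#' m <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' sd <- data.frame(sample_id = colnames(m),
#'                  subject_id = rep(c("P1", "P2"), each = 2),
#'                  group = "BER", stimulation = c("EW", "M"),
#'                  gender = "F", batch = "B1")
#' se <- StimExperiment(m, sd)
#' @export
StimExperiment <- function(exprs, sampleData) {
  stopifnot(is.matrix(exprs), !is.null(rownames(exprs)),
            !is.null(colnames(exprs)))
  sampleData <- as.data.frame(sampleData)
  if (!is.null(sampleData$sample_id))
    rownames(sampleData) <- sampleData$sample_id
  if (!all(colnames(exprs) %in% rownames(sampleData)))
    stop("every expression column must have a metadata row")
  sampleData <- sampleData[colnames(exprs), , drop = FALSE]
  sampleData$group <- toupper(as.character(sampleData$group))
  sampleData$stimulation <- toupper(as.character(sampleData$stimulation))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs),
    colData = S4Vectors::DataFrame(sampleData))
  methods::new("StimExperiment", se)
}

#' Expression matrix of a StimExperiment
#' @param x a \linkS4class{StimExperiment}.
#' @return numeric matrix, genes x samples.
#' @export
exprsMatrix <- function(x) SummarizedExperiment::assay(x, "exprs")

#' Sample metadata of a StimExperiment
#' @param x a \linkS4class{StimExperiment}.
#' @return data.frame of per-sample design variables.
#' @export
sampleData <- function(x) as.data.frame(SummarizedExperiment::colData(x))

setMethod("show", "StimExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("StimExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
  if (nrow(cd)) {
    cat("  groups:      ", paste(sprintf("%s=%d", names(table(cd$group)),
                                         table(cd$group)), collapse = " "), "\n")
    cat("  stimulation: ", paste(sprintf("%s=%d", names(table(cd$stimulation)),
                                         table(cd$stimulation)), collapse = " "),
        "\n")
  }
  invisible(NULL)
})

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (gene ids). Duplicate members
#'   within a set are removed.
#' @param name collection name.
#' @param source free-text source tag (e.g. \code{"hallmark"}, \code{"C7"}).
#' @return A \linkS4class{GeneSetCollection}.
#' @export
geneSets <- function(sets, name = "collection", source = "") {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  methods::new("GeneSetCollection", name = name, sets = sets, source = source)
}

#' @describeIn geneSets number of sets in the collection.
#' @param x a \linkS4class{GeneSetCollection}.
#' @export
nSets <- function(x) length(x@sets)

#' @describeIn geneSets named list of member vectors.
#' @export
setMembers <- function(x) x@sets

setMethod("show", "GeneSetCollection", function(object) {
  sz <- vapply(object@sets, length, integer(1))
  cat("GeneSetCollection '", object@name, "' (", object@source, "): ",
      length(sz), " sets", sep = "")
  if (length(sz)) cat(", sizes ", min(sz), "-", max(sz), sep = "")
  cat("\n")
  invisible(NULL)
})

setMethod("names", "GeneSetCollection", function(x) names(x@sets))
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

#' Construct an annotation map
#'
#' @param assignments data.frame with columns \code{level}, \code{signature},
#'   \code{category} (one row per signature per level).
#' @return An \linkS4class{AnnotationMap}.
#' @export
annotationMap <- function(assignments) {
  assignments <- as.data.frame(assignments)
  assignments$level <- as.integer(assignments$level)
  assignments$signature <- as.character(assignments$signature)
  assignments$category <- as.character(assignments$category)
  methods::new("AnnotationMap",
               assignments = assignments[c("level", "signature", "category")])
}

#' Annotation levels present in a map
#' @param map an \linkS4class{AnnotationMap}.
#' @return sorted integer vector of levels.
#' @export
annotationLevels <- function(map) sort(unique(map@assignments$level))

#' Signature -> category assignments at one level
#' @param map an \linkS4class{AnnotationMap}.
#' @param level annotation level (1-4).
#' @return named character vector: names are signatures, values categories.
#' @export
levelAssignments <- function(map, level) {
  a <- map@assignments[map@assignments$level == level, ]
  setNames(a$category, a$signature)
}

setMethod("show", "AnnotationMap", function(object) {
  a <- object@assignments
  cat("AnnotationMap:", nrow(a), "assignments over",
      length(unique(a$level)), "level(s)\n")
  for (lv in sort(unique(a$level))) {
    al <- a[a$level == lv, ]
    cat(sprintf("  level %d: %d signatures in %d categories\n", lv,
                nrow(al), length(unique(al$category))))
  }
  invisible(NULL)
})

#' Construct a module partition
#' @param assignment named integer vector gene id -> module label (0 =
#'   unassigned). Labels are renumbered to decreasing size order.
#' @return A \linkS4class{ModulePartition}.
#' @export
modulePartition <- function(assignment) {
  methods::new("ModulePartition",
               assignment = .renumberBySize(assignment))
}

# renumber positive labels 1..K by decreasing module size (ties: smaller
# original label first); 0 stays 0
.renumberBySize <- function(assignment) {
  a <- as.integer(assignment)
  names(a) <- names(assignment)
  pos <- a[a > 0L]
  if (!length(pos)) return(a)
  tab <- table(pos)
  ord <- order(-as.integer(tab), as.integer(names(tab)))
  relab <- setNames(seq_along(ord), names(tab)[ord])
  a[a > 0L] <- relab[as.character(pos)]
  a
}

#' Module assignment vector
#' @param partition a \linkS4class{ModulePartition}.
#' @return named integer vector gene -> module label.
#' @export
moduleAssignment <- function(partition) partition@assignment

#' Module sizes
#' @param partition a \linkS4class{ModulePartition}.
#' @return named integer vector of sizes of assigned modules (label order).
#' @export
moduleSizes <- function(partition) {
  a <- partition@assignment
  tab <- table(a[a > 0L])
  setNames(as.integer(tab), names(tab))
}

#' Genes belonging to one module
#' @param partition a \linkS4class{ModulePartition}.
#' @param module module label.
#' @return character vector of gene ids.
#' @export
moduleGenes <- function(partition, module) {
  a <- partition@assignment
  names(a)[a == module]
}

setMethod("show", "ModulePartition", function(object) {
  sz <- moduleSizes(object)
  n0 <- sum(object@assignment == 0L)
  cat("ModulePartition:", length(sz), "modules,", n0, "unassigned genes\n")
  if (length(sz))
    cat("  sizes:", paste(sz, collapse = " "), "\n")
  invisible(NULL)
})

#' Construct a contrast specification
#'
#' @param family one of \code{"between_group_within_condition"},
#'   \code{"within_group_EW_vs_M"}, \code{"difference_of_differences"}.
#' @param groupA focal group (its coefficient is the reported log2FC).
#' @param groupB reference group (omit for family 2).
#' @param condition stimulation condition, family 1 only.
#' @return A \linkS4class{ContrastSpec}.
#' @examples
#' contrastSpec("difference_of_differences", "BER", "AC")
#' contrastSpec("within_group_EW_vs_M", "BER")
#' contrastSpec("between_group_within_condition", "BER", "AC", "EW")
#' @export
contrastSpec <- function(family, groupA, groupB = NA_character_,
                         condition = NA_character_) {
  methods::new("ContrastSpec", family = family,
               groupA = toupper(groupA),
               groupB = if (is.na(groupB)) NA_character_ else toupper(groupB),
               condition = if (is.na(condition)) NA_character_
                           else toupper(condition))
}

#' Human-readable contrast id
#' @param contrast a \linkS4class{ContrastSpec}.
#' @return character scalar such as \code{"dd_BERvsAC"}.
#' @export
contrastId <- function(contrast) {
  switch(contrast@family,
         between_group_within_condition =
           sprintf("%s_%svs%s", contrast@condition, contrast@groupA,
                   contrast@groupB),
         within_group_EW_vs_M = sprintf("EWvsM_%s", contrast@groupA),
         difference_of_differences =
           sprintf("dd_%svs%s", contrast@groupA, contrast@groupB))
}

setMethod("show", "ContrastSpec", function(object) {
  cat("ContrastSpec:", contrastId(object), "(", object@family, ")\n")
  invisible(NULL)
})

#' Gene ids of a DEG signature
#' @param signature a \linkS4class{DEGSignature}.
#' @return ordered character vector of gene ids.
#' @export
signatureGenes <- function(signature) signature@geneIds

#' Direction tag of a DEG signature
#' @param signature a \linkS4class{DEGSignature}.
#' @return \code{"up"} or \code{"down"}.
#' @export
signatureDirection <- function(signature) signature@direction

setMethod("show", "DEGSignature", function(object) {
  cat("DEGSignature ", object@contrastId, " [", object@direction, "]: ",
      length(object@geneIds), " genes\n", sep = "")
  invisible(NULL)
})

setMethod("length", "DEGSignature", function(x) length(x@geneIds))
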