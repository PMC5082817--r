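#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor lm mad median p.adjust phyper pnorm prcomp pt quantile
#'   rbinom rnorm runif sd setNames complete.cases as.dist cutree hclust
#'   model.matrix var
#' @importFrom utils head read.delim write.table
NULL

#' StimExperiment: paired stimulation expression container
#'
#' A thin \linkS4class{SummarizedExperiment} subclass for log2-scale
#' normalized expression of PBMC samples cultured with an antigen (stimulated,
#' \code{"EW"}) or with media alone (\code{"M"}). The \code{colData} must carry
#' the study design: subject, clinical group (\code{AC}, \code{BET},
#' \code{BER}), stimulation condition, gender and hybridization batch.
#'
#' @slot .. inherits all slots from \code{SummarizedExperiment}; the first
#'   assay (\code{"exprs"}) holds finite log2 intensities, rows are genes.
#'
#' @seealso [StimExperiment()] for construction, [simulateExpression()] for a
#'   synthetic instance with planted ground truth.
#' @export
setClass("StimExperiment", contains = "SummarizedExperiment")

.VALID_GROUPS <- c("AC", "BET", "BER")
.VALID_STIM <- c("EW", "M")

setValidity("StimExperiment", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject_id", "group", "stimulation", "gender", "batch")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData missing column(s): ",
                         paste(miss, collapse = ", ")))
  if (!length(msg)) {
    if (!all(cd$group %in% .VALID_GROUPS))
      msg <- c(msg, "group must be one of AC, BET, BER")
    if (!all(cd$stimulation %in% .VALID_STIM))
      msg <- c(msg, "stimulation must be EW or M")
    key <- paste(cd$subject_id, cd$stimulation)
    if (anyDuplicated(key))
      msg <- c(msg, "each (subject, stimulation) pair may appear at most once")
  }
  if (length(SummarizedExperiment::assays(object))) {
    m <- SummarizedExperiment::assay(object, 1L)
    if (anyDuplicated(rownames(m)))
      msg <- c(msg, "duplicate gene ids in rownames")
    if (!all(is.finite(m)))
      msg <- c(msg, "expression values must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Named gene-set collection (GMT-style)
#'
#' Holds named gene sets as character vectors of unique gene ids, plus a
#' collection name and a free-text source tag (e.g. \code{"hallmark"},
#' \code{"C7"}).
#'
#' @slot name single character, collection name.
#' @slot sets named list of character vectors; members unique, sets non-empty.
#' @slot source single character source tag.
#'
#' @seealso [readGmt()], [writeGmt()], [geneSets()], [enrichCollection()]
#' @export
setClass("GeneSetCollection",
         representation(name = "character", sets = "list",
                        source = "character"),
         prototype(name = "collection", sets = list(), source = ""))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "name must be length 1")
  s <- object@sets
  if (length(s)) {
    if (is.null(names(s)) || anyDuplicated(names(s)) || any(names(s) == ""))
      msg <- c(msg, "sets must have unique non-empty names")
    if (!all(vapply(s, is.character, logical(1))))
      msg <- c(msg, "each set must be a character vector")
    if (any(vapply(s, length, integer(1)) == 0L))
      msg <- c(msg, "sets must be non-empty")
    if (any(vapply(s, anyDuplicated, integer(1)) > 0L))
      msg <- c(msg, "set members must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Signature-to-category annotation map
#'
#' Assigns immunologic signatures to functional categories at one or more
#' annotation levels (1 = cell type, 2 = cell subset, 3 = activation state,
#' 4 = myeloid TLR stimulation). A signature maps to at most one category per
#' level; signatures absent from a level are excluded from that level's
#' enrichment universe.
#'
#' @slot assignments data.frame with columns \code{level} (integer),
#'   \code{signature} and \code{category} (character).
#'
#' @seealso [annotationMap()], [readAnnotation()], [runAnnotationLevel()]
#' @export
setClass("AnnotationMap",
         representation(assignments = "data.frame"),
         prototype(assignments = data.frame(level = integer(),
                                            signature = character(),
                                            category = character())))

setValidity("AnnotationMap", function(object) {
  a <- object@assignments
  msg <- character()
  if (!all(c("level", "signature", "category") %in% colnames(a)))
    return("assignments needs columns level, signature, category")
  if (nrow(a)) {
    if (!all(a$level %in% 1:4)) msg <- c(msg, "level must be in 1..4")
    if (anyDuplicated(paste(a$level, a$signature)))
      msg <- c(msg, "a signature maps to at most one category per level")
    if (any(a$category == "")) msg <- c(msg, "categories must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' Gene-to-module partition
#'
#' Result of co-expression module detection: an integer module label per gene,
#' with 0 marking unassigned (background) genes. Assigned modules are numbered
#' in decreasing size order (module 1 is the largest).
#'
#' @slot assignment named integer vector, gene id -> module label (0 =
#'   unassigned).
#'
#' @seealso [detectModules()], [mergeModules()], [moduleSizes()]
#' @export
setClass("ModulePartition",
         representation(assignment = "integer"),
         prototype(assignment = setNames(integer(), character())))

setValidity("ModulePartition", function(object) {
  a <- object@assignment
  msg <- character()
  if (length(a) && (is.null(names(a)) || anyDuplicated(names(a))))
    msg <- c(msg, "assignment must be named by unique gene ids")
  if (length(a) && any(a < 0L))
    msg <- c(msg, "module labels must be >= 0")
  lab <- sort(unique(a[a > 0L]))
  if (length(lab) && !identical(lab, seq_along(lab)))
    msg <- c(msg, "module labels must be consecutive 1..K")
  if (length(msg)) msg else TRUE
})

#' Contrast specification for differential expression
#'
#' The three contrast families of the study design:
#' \describe{
#'   \item{\code{between_group_within_condition}}{group A vs group B within a
#'     single stimulation condition.}
#'   \item{\code{within_group_EW_vs_M}}{paired stimulation effect (EW - M)
#'     within one group.}
#'   \item{\code{difference_of_differences}}{interaction: does the EW - M
#'     response differ between group A and group B.}
#' }
#'
#' @slot family contrast family (one of the three above).
#' @slot groupA,groupB clinical group codes; \code{groupB} unused for family 2.
#' @slot condition stimulation condition for family 1 (\code{"EW"} or
#'   \code{"M"}).
#'
#' @seealso [contrastSpec()], [fitContrast()]
#' @export
setClass("ContrastSpec",
         representation(family = "character", groupA = "character",
                        groupB = "character", condition = "character"))

.CONTRAST_FAMILIES <- c("between_group_within_condition",
                        "within_group_EW_vs_M",
                        "difference_of_differences")

setValidity("ContrastSpec", function(object) {
  msg <- character()
  if (!object@family %in% .CONTRAST_FAMILIES)
    msg <- c(msg, paste("family must be one of:",
                        paste(.CONTRAST_FAMILIES, collapse = ", ")))
  if (!object@groupA %in% .VALID_GROUPS)
    msg <- c(msg, "groupA must be AC, BET or BER")
  if (object@family != "within_group_EW_vs_M") {
    if (!object@groupB %in% .VALID_GROUPS)
      msg <- c(msg, "groupB must be AC, BET or BER")
    else if (identical(object@groupA, object@groupB))
      msg <- c(msg, "groups must be distinct")
  }
  if (object@family == "between_group_within_condition" &&
      !object@condition %in% .VALID_STIM)
    msg <- c(msg, "condition must be EW or M for family 1")
  if (length(msg)) msg else TRUE
})

#' Direction-tagged standardized DEG signature
#'
#' An ordered gene list (largest absolute fold change first), at most
#' \code{nTop} genes, drawn from one direction (up- or down-regulated) of one
#' contrast. Signature sizes are standardized so enrichment results are
#' comparable across contrasts.
#'
#' @slot contrastId character label of the originating contrast.
#' @slot direction \code{"up"} or \code{"down"}.
#' @slot geneIds ordered character vector of unique gene ids.
#'
#' @seealso [standardizeSignature()]
#' @export
setClass("DEGSignature",
         representation(contrastId = "character", direction = "character",
                        geneIds = "character"))

setValidity("DEGSignature", function(object) {
  msg <- character()
  if (!object@direction %in% c("up", "down"))
    msg <- c(msg, "direction must be 'up' or 'down'")
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, "gene ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration with planted ground truth
#'
#' Parameters of the synthetic-data generator emulating a paired
#' stimulated/unstimulated PBMC study across three clinical groups. See
#' [simulationConfig()] for defaults and units.
#'
#' @slot nSubjects named integer (AC, BET, BER) subjects per group.
#' @slot nGenes,nDEGenes gene universe size and number of planted
#'   stimulation-responsive genes.
#' @slot deLog2FC planted EW - M shift (log2 units) in the responsive groups.
#' @slot deGroups groups in which the planted shift is expressed.
#' @slot moduleSizes integer vector of planted co-expression module sizes.
#' @slot moduleCor target within-module pairwise Pearson correlation in (0,1).
#' @slot noiseSd residual SD of log2 expression.
#' @slot nSignatures,nCategories immunologic signature collection geometry.
#' @slot signatureSize genes per signature.
#' @slot plantedCategory category id whose signatures overlap the planted DE
#'   genes; \code{plantedOverlap} is the fraction of each planted signature
#'   drawn from the DE set.
#' @slot cytokineEffects named list: cytokine -> named numeric of per-group
#'   log10 pg/ml EW shifts (groups absent from the vector get 0).
#' @slot cytokineNoiseSd log10-scale residual SD of cytokine responses.
#' @slot detectionFloor assay detection floor in pg/ml; values below are
#'   clamped.
#' @slot seed integer seed; fully determines all generator output.
#' @export
setClass("SimulationConfig",
         representation(nSubjects = "integer", nGenes = "integer",
                        nDEGenes = "integer", deLog2FC = "numeric",
                        deGroups = "character",
                        moduleSizes = "integer", moduleCor = "numeric",
                        noiseSd = "numeric",
                        nSignatures = "integer", nCategories = "integer",
                        signatureSize = "integer", plantedOverlap = "numeric",
                        plantedCategory = "character",
                        cytokineEffects = "list",
                        cytokineNoiseSd = "numeric",
                        detectionFloor = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (!identical(sort(names(object@nSubjects)), sort(.VALID_GROUPS)))
    msg <- c(msg, "nSubjects must be named AC, BET, BER")
  if (any(object@nSubjects < 1L)) msg <- c(msg, "nSubjects must be >= 1")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@nDEGenes < 0L || object@nDEGenes > object@nGenes)
    msg <- c(msg, "nDEGenes must be in [0, nGenes]")
  if (length(object@moduleSizes) && sum(object@moduleSizes) > object@nGenes)
    msg <- c(msg, "module sizes must sum to <= nGenes")
  if (object@moduleCor <= 0 || object@moduleCor >= 1)
    msg <- c(msg, "moduleCor must be in (0,1)")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
  if (!all(object@deGroups %in% .VALID_GROUPS))
    msg <- c(msg, "deGroups must be a subset of AC, BET, BER")
  if (object@nSignatures < 1L || object@nCategories < 1L)
    msg <- c(msg, "nSignatures and nCategories must be >= 1")
  if (object@plantedOverlap < 0 || object@plantedOverlap > 1)
    msg <- c(msg, "plantedOverlap must be in [0,1]")
  if (object@detectionFloor < 0)
    msg <- c(msg, "detectionFloor must be >= 0")
  if (length(msg)) msg else TRUE
})
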