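#' Pipeline configuration
#'
#' Collects inputs and thresholds for an end-to-end run. Either a
#' \code{simulation} block or the file-based inputs (\code{expressionPath} +
#' \code{metadataPath}, optionally \code{gmtPath}, \code{annotationPath},
#' \code{cytokinePath}) must be present.
#'
#' @param simulation a \linkS4class{SimulationConfig}, or \code{NULL} for
#'   file-based input.
#' @param expressionPath,metadataPath,gmtPath,annotationPath,cytokinePath
#'   input file paths (ignored when \code{simulation} is given).
#' @param contrasts list of \linkS4class{ContrastSpec}; \code{NULL} selects
#'   the study's default set (EW vs M within each group plus the
#'   difference-of-differences contrasts against AC).
#' @param firstStageFdr first-stage annotation significance gate.
#' @param nSignificant,nTop signature standardization sizes.
#' @param beta soft-thresholding power for the co-expression network.
#' @param minModuleSize,mergeCutoff module detection and merge parameters.
#' @param reportingFdr FDR threshold used in run summaries.
#' @param annotationLevels annotation levels to score.
#' @param seed integer seed recorded in the report; for simulation runs it
#'   overrides the simulation config's seed.
#' @return a list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(simulation = NULL,
                           expressionPath = NULL, metadataPath = NULL,
                           gmtPath = NULL, annotationPath = NULL,
                           cytokinePath = NULL,
                           contrasts = NULL,
                           firstStageFdr = 0.01,
                           nSignificant = 500L, nTop = 200L,
                           beta = 7, minModuleSize = 50L,
                           mergeCutoff = 0.29,
                           reportingFdr = 0.05,
                           annotationLevels = NULL,
                           seed = 1L) {
  if (is.null(simulation) &&
      (is.null(expressionPath) || is.null(metadataPath)))
    stop("either a simulation block or expression+metadata paths required")
  stopifnot(firstStageFdr > 0, nSignificant > 0, nTop > 0, beta > 0,
            minModuleSize > 0, mergeCutoff > 0, reportingFdr > 0)
  cfg <- list(simulation = simulation,
              expressionPath = expressionPath, metadataPath = metadataPath,
              gmtPath = gmtPath, annotationPath = annotationPath,
              cytokinePath = cytokinePath,
              contrasts = contrasts,
              firstStageFdr = firstStageFdr,
              nSignificant = as.integer(nSignificant),
              nTop = as.integer(nTop),
              beta = beta, minModuleSize = as.integer(minModuleSize),
              mergeCutoff = mergeCutoff, reportingFdr = reportingFdr,
              annotationLevels = annotationLevels,
              seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

.defaultContrasts <- function(groups) {
  pairs <- Filter(function(p) all(p %in% groups),
                  list(c("BER", "AC"), c("BET", "AC"), c("BER", "BET")))
  c(unlist(lapply(c("EW", "M"), function(cond)
      lapply(pairs, function(p)
        contrastSpec("between_group_within_condition", p[1], p[2], cond))),
    recursive = FALSE),
    lapply(groups, function(g) contrastSpec("within_group_EW_vs_M", g)),
    lapply(pairs, function(p)
      contrastSpec("difference_of_differences", p[1], p[2])))
}

.configHash <- function(config) {
  # small deterministic fingerprint of the serialized config (djb2)
  bytes <- as.integer(serialize(unclass(config), NULL, version = 2L))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Sequences all stages: simulate (or load) inputs, fit every contrast,
#' standardize up/down signatures, enrich signatures against the gene-set
#' collection, score every annotation level by the enrichment-of-enrichment
#' procedure, build the co-expression network (soft power, TOM,
#' module detection, eigengenes, merging), associate module eigengene deltas
#' with cytokine deltas, and fit robust cytokine group effects. Identical
#' config and seed give identical report tables. Stages without inputs
#' (e.g. no cytokine table) are skipped and noted.
#'
#' @param config a \code{"PipelineConfig"} from [pipelineConfig()].
#' @return a list of class \code{"RunReport"}: \code{deg} (named list of DEG
#'   tables), \code{signatures}, \code{enrichment}, \code{annotation} (per
#'   level), \code{partition}, \code{eigengenes},
#'   \code{module_associations}, \code{module_signature_enrichment},
#'   \code{cytokine_fits}, \code{truth} (simulation runs only),
#'   \code{provenance} (config hash, seed, thresholds, skipped stages).
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(simulation = simulationConfig(
#'   nSubjects = c(AC = 5, BET = 5, BER = 8), nGenes = 400, nDEGenes = 40,
#'   moduleSizes = c(60L, 60L), nSignatures = 40L, nCategories = 8L,
#'   signatureSize = 40L, seed = 11), minModuleSize = 30L, seed = 11)
#' rep <- runPipeline(cfg)
#' names(rep)
#' }
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  skipped <- character()
  truth <- NULL
  collection <- NULL
  annotation <- NULL
  cytokines <- NULL

  if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim@seed <- config$seed
    study <- .stage("simulate", simulateStudy(sim))
    experiment <- study$experiment
    truth <- study$truth
    collection <- study$collection
    annotation <- study$annotation
    cytokines <- study$cytokines
  } else {
    experiment <- .stage("load", {
      m <- readExpression(config$expressionPath)
      md <- readMetadata(config$metadataPath)
      StimExperiment(m, md)
    })
    if (!is.null(config$gmtPath))
      collection <- .stage("load_gmt", readGmt(config$gmtPath))
    if (!is.null(config$annotationPath))
      annotation <- .stage("load_annotation",
                           readAnnotation(config$annotationPath))
    if (!is.null(config$cytokinePath))
      cytokines <- .stage("load_cytokines",
                          readCytokines(config$cytokinePath))
  }
  universe <- rownames(experiment)
  samples <- sampleData(experiment)
  if (is.null(samples$sample_id)) samples$sample_id <- rownames(samples)

  groups <- intersect(.VALID_GROUPS, unique(samples$group))
  contrasts <- config$contrasts %||% .defaultContrasts(groups)
  deg <- .stage("deg", {
    out <- lapply(contrasts, function(ct) fitContrast(experiment, ct))
    names(out) <- vapply(contrasts, contrastId, character(1))
    out
  })

  signatures <- .stage("signatures", {
    sigs <- list()
    for (nm in names(deg)) {
      for (dir in c("up", "down")) {
        sg <- standardizeSignature(deg[[nm]], dir, config$nSignificant,
                                   config$nTop)
        if (length(sg)) sigs[[paste0(nm, "_", dir)]] <- sg
      }
    }
    sigs
  })

  enrichment <- NULL
  annotationScores <- NULL
  if (!is.null(collection)) {
    enrichment <- .stage("enrichment", {
      do.call(rbind, lapply(signatures, function(sg)
        enrichCollection(sg, collection, universe)))
    })
    if (!is.null(annotation)) {
      levels <- config$annotationLevels %||% annotationLevels(annotation)
      annotationScores <- .stage("annotation", {
        out <- list()
        for (lv in levels) {
          perSig <- lapply(names(signatures), function(nm) {
            tab <- runAnnotationLevel(signatures[[nm]], collection,
                                      annotation, lv, universe,
                                      config$firstStageFdr)
            if (nrow(tab)) cbind(signature_id = nm, tab) else NULL
          })
          out[[as.character(lv)]] <-
            do.call(rbind, perSig[!vapply(perSig, is.null, logical(1))])
        }
        out
      })
    } else skipped <- c(skipped, "annotation")
  } else skipped <- c(skipped, "enrichment", "annotation")

  coex <- .stage("coexpression", {
    adj <- softAdjacency(exprsMatrix(experiment), config$beta)
    tom <- topologicalOverlap(adj)
    part <- detectModules(1 - tom, config$minModuleSize)
    if (length(moduleSizes(part)) >= 2L)
      part <- mergeModules(exprsMatrix(experiment), part,
                           config$mergeCutoff)
    me <- if (length(moduleSizes(part)))
      moduleEigengenes(exprsMatrix(experiment), part) else NULL
    list(partition = part, eigengenes = me)
  })

  modSigEnrich <- NULL
  if (length(signatures) && length(moduleSizes(coex$partition)))
    modSigEnrich <- .stage("module_signature_enrichment",
      moduleSignatureEnrichment(coex$partition, signatures, universe))

  moduleAssoc <- NULL
  cytokineFits <- NULL
  if (!is.null(cytokines)) {
    cytokineFits <- .stage("cytokine_fits", fitCytokineGroups(cytokines))
    if (!is.null(coex$eigengenes)) {
      moduleAssoc <- .stage("module_associations", {
        dl <- computeDelta(cytokines)
        dl$tdelta <- log10TransformDelta(dl$delta)
        wide <- do.call(cbind, lapply(split(dl, dl$cytokine), function(d)
          setNames(d$tdelta, d$subject_id)[unique(dl$subject_id)]))
        rownames(wide) <- unique(dl$subject_id)
        med <- eigengeneDeltas(coex$eigengenes, samples)
        shared <- intersect(colnames(med), rownames(wide))
        moduleTraitAssociation(med[, shared, drop = FALSE],
                               wide[shared, , drop = FALSE])
      })
    }
  } else skipped <- c(skipped, "cytokines")

  report <- list(deg = deg, signatures = signatures,
                 enrichment = enrichment, annotation = annotationScores,
                 partition = coex$partition, eigengenes = coex$eigengenes,
                 module_signature_enrichment = modSigEnrich,
                 module_associations = moduleAssoc,
                 cytokine_fits = cytokineFits,
                 truth = truth,
                 provenance = list(
                   config_hash = .configHash(config),
                   seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("StimProfiler")),
                   thresholds = config[c("firstStageFdr", "nSignificant",
                                         "nTop", "beta", "minModuleSize",
                                         "mergeCutoff", "reportingFdr")],
                   skipped = skipped))
  class(report) <- "RunReport"
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport (seed ", x$provenance$seed, ", config ",
      x$provenance$config_hash, ")\n", sep = "")
  cat("  contrasts: ", paste(names(x$deg), collapse = ", "), "\n")
  cat("  signatures:", length(x$signatures), "\n")
  if (!is.null(x$partition)) {
    sz <- moduleSizes(x$partition)
    cat("  modules:   ", length(sz),
        if (length(sz)) paste0(" (sizes ", paste(sz, collapse = "/"), ")"),
        "\n", sep = "")
  }
  if (length(x$provenance$skipped))
    cat("  skipped:   ", paste(x$provenance$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Write all report tables to a directory
#'
#' Tab-delimited outputs at full precision, plus a run log with the seed,
#' thresholds, config hash and any skipped stages.
#'
#' @param report a \code{"RunReport"}.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeReport <- function(report, dir) {
  stopifnot(inherits(report, "RunReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$deg))
    writeTsv(report$deg[[nm]], file.path(dir, paste0("deg_", nm, ".tsv")))
  if (!is.null(report$enrichment))
    writeTsv(report$enrichment, file.path(dir, "enrichment.tsv"))
  if (!is.null(report$annotation))
    for (lv in names(report$annotation))
      if (!is.null(report$annotation[[lv]]))
        writeTsv(report$annotation[[lv]],
                 file.path(dir, paste0("annotation_level", lv, ".tsv")))
  if (!is.null(report$partition)) {
    a <- moduleAssignment(report$partition)
    writeTsv(data.frame(gene_id = names(a), module_label = unname(a)),
             file.path(dir, "modules.tsv"))
  }
  if (!is.null(report$eigengenes)) {
    eg <- data.frame(module = rownames(report$eigengenes),
                     report$eigengenes, check.names = FALSE)
    writeTsv(eg, file.path(dir, "eigengenes.tsv"))
  }
  if (!is.null(report$module_associations))
    writeTsv(report$module_associations,
             file.path(dir, "module_associations.tsv"))
  if (!is.null(report$module_signature_enrichment))
    writeTsv(report$module_signature_enrichment,
             file.path(dir, "module_signature_enrichment.tsv"))
  if (!is.null(report$cytokine_fits))
    writeTsv(report$cytokine_fits, file.path(dir, "cytokine_fits.tsv"))
  log <- c(paste("seed:", report$provenance$seed),
           paste("config_hash:", report$provenance$config_hash),
           paste("package_version:", report$provenance$package_version),
           vapply(names(report$provenance$thresholds), function(nm)
             paste0(nm, ": ", report$provenance$thresholds[[nm]]),
             character(1)),
           paste("skipped:", paste(report$provenance$skipped,
                                   collapse = ", ")))
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
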