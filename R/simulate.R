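#' Simulation configuration for a paired stimulation study
#'
#' Builds a \linkS4class{SimulationConfig} describing a synthetic study with
#' planted ground truth. Defaults emulate the design of a paired
#' egg-white (EW) vs media (M) PBMC study across three clinical groups:
#' 14 AC, 20 BET and 34 BER subjects with expression data, a ~20k-gene array
#' space scaled down to 2000 genes, stimulation-responsive genes at +1 log2
#' fold change in the allergic (BER, BET) groups, three co-expressed modules
#' of 100 genes at within-module correlation 0.8, an immunologic signature
#' collection of 100 signatures in 20 categories with one planted enriched
#' category, and cytokine responses on the log10 pg/ml scale with a
#' detection floor of 0.5 pg/ml (allergic-group shifts for IL-5, IL-9 and
#' TNFa; null cytokines alongside).
#'
#' @param nSubjects named integer vector: subjects per clinical group.
#' @param nGenes number of genes.
#' @param nDEGenes number of planted stimulation-responsive genes.
#' @param deLog2FC planted EW - M mean shift in log2 units.
#' @param deGroups groups expressing the planted shift.
#' @param moduleSizes sizes of planted co-expression modules.
#' @param moduleCor target pairwise within-module correlation, in (0,1).
#' @param noiseSd residual SD of log2 expression.
#' @param nSignatures,nCategories signature collection geometry; categories
#'   receive \code{nSignatures / nCategories} signatures each (remainder goes
#'   to the last category).
#' @param signatureSize genes per signature.
#' @param plantedOverlap fraction of each planted signature's members drawn
#'   from the planted DE genes.
#' @param plantedCategory id of the category holding the planted signatures.
#' @param cytokineEffects named list: cytokine -> named numeric vector of
#'   per-group EW shifts in log10 pg/ml. Cytokines with an empty vector are
#'   nulls.
#' @param cytokineNoiseSd log10-scale residual SD of the cytokine response.
#' @param detectionFloor assay floor in pg/ml; simulated concentrations are
#'   clamped at this value.
#' @param seed integer seed; identical configs give byte-identical output.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(seed = 1)
#' cfg
#' @export
simulationConfig <- function(
    nSubjects = c(AC = 14L, BET = 20L, BER = 34L),
    nGenes = 2000L,
    nDEGenes = 100L,
    deLog2FC = 1,
    deGroups = c("BER", "BET"),
    moduleSizes = c(100L, 100L, 100L),
    moduleCor = 0.8,
    noiseSd = 0.5,
    nSignatures = 100L,
    nCategories = 20L,
    signatureSize = 100L,
    plantedOverlap = 0.6,
    plantedCategory = "C01",
    cytokineEffects = list(
      `IL-9`  = c(BER = 1.0, BET = 0.8),
      `TNFa`  = c(BER = 1.0, BET = 0.7),
      `IL-5`  = c(BER = 0.8, BET = 0.6),
      `IFNg`  = numeric(),
      `IL-10` = numeric(),
      `IL-6`  = numeric()),
    cytokineNoiseSd = 0.3,
    detectionFloor = 0.5,
    seed = 1L) {
  methods::new("SimulationConfig",
               nSubjects = setNames(as.integer(nSubjects), names(nSubjects)),
               nGenes = as.integer(nGenes),
               nDEGenes = as.integer(nDEGenes),
               deLog2FC = as.numeric(deLog2FC),
               deGroups = as.character(deGroups),
               moduleSizes = as.integer(moduleSizes),
               moduleCor = as.numeric(moduleCor),
               noiseSd = as.numeric(noiseSd),
               nSignatures = as.integer(nSignatures),
               nCategories = as.integer(nCategories),
               signatureSize = as.integer(signatureSize),
               plantedOverlap = as.numeric(plantedOverlap),
               plantedCategory = as.character(plantedCategory),
               cytokineEffects = cytokineEffects,
               cytokineNoiseSd = as.numeric(cytokineNoiseSd),
               detectionFloor = as.numeric(detectionFloor),
               seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig (seed ", object@seed, ")\n", sep = "")
  cat("  subjects: ", paste(sprintf("%s=%d", names(object@nSubjects),
                                    object@nSubjects), collapse = " "), "\n")
  cat("  genes: ", object@nGenes, " (", object@nDEGenes, " DE at log2FC ",
      object@deLog2FC, " in ", paste(object@deGroups, collapse = "/"),
      ")\n", sep = "")
  cat("  modules: ", paste(object@moduleSizes, collapse = "/"),
      " at cor ", object@moduleCor, "\n", sep = "")
  cat("  signatures: ", object@nSignatures, " in ", object@nCategories,
      " categories (planted: ", object@plantedCategory, ")\n", sep = "")
  invisible(NULL)
})

# subject-level design table: one row per subject
.subjectTable <- function(config) {
  groups <- rep(names(config@nSubjects), config@nSubjects)
  n <- length(groups)
  data.frame(
    subject_id = sprintf("SUBJ%03d", seq_len(n)),
    group = groups,
    gender = ifelse(rbinom(n, 1L, 0.5) == 1L, "F", "M"),
    batch = paste0("B", ((seq_len(n) - 1L) %% 5L) + 1L),
    stringsAsFactors = FALSE)
}

#' Simulate a paired-stimulation expression experiment
#'
#' Generates a \linkS4class{StimExperiment} with two samples (EW and M) per
#' subject and planted ground truth: stimulation-responsive genes whose mean
#' EW - M difference is \code{deLog2FC} in the designated groups only, and
#' co-expression modules built from one latent factor per module with loading
#' \code{sqrt(moduleCor)} (giving expected pairwise correlation
#' \code{moduleCor}). Gender and hybridization batch are assigned per subject
#' and injected as small additive offsets so covariate adjustment is
#' exercised in between-group fits; because both of a subject's samples share
#' these offsets, they cancel exactly in paired EW - M deltas.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{experiment} (a
#'   \linkS4class{StimExperiment}) and \code{truth} (a list with
#'   \code{de_genes}, \code{de_contrasts}, \code{module_assignment},
#'   \code{latent_factors} [module x sample matrix]).
#' @examples
#' sim <- simulateExpression(simulationConfig(
#'   nSubjects = c(AC = 4, BET = 4, BER = 4), nGenes = 200,
#'   nDEGenes = 20, moduleSizes = c(30, 30), seed = 7))
#' sim$experiment
#' @export
simulateExpression <- function(config) {
  methods::validObject(config)
  set.seed(config@seed)
  subj <- .subjectTable(config)
  nSub <- nrow(subj)
  samples <- data.frame(
    sample_id = paste0(rep(subj$subject_id, each = 2L), "_",
                       rep(c("EW", "M"), nSub)),
    subject_id = rep(subj$subject_id, each = 2L),
    group = rep(subj$group, each = 2L),
    stimulation = rep(c("EW", "M"), nSub),
    gender = rep(subj$gender, each = 2L),
    batch = rep(subj$batch, each = 2L),
    stringsAsFactors = FALSE)
  nSamp <- nrow(samples)
  genes <- sprintf("GENE%05d", seq_len(config@nGenes))

  # gene-level baselines on the log2 intensity scale (array-like 6..12)
  baseline <- rnorm(config@nGenes, mean = 8, sd = 1.5)
  Y <- matrix(baseline, config@nGenes, nSamp)
  dimnames(Y) <- list(genes, samples$sample_id)

  # planted modules: latent factor per module, shared across that module's
  # genes with loading sqrt(moduleCor); residual completes unit variance
  nMod <- length(config@moduleSizes)
  moduleAssign <- setNames(integer(config@nGenes), genes)
  latent <- NULL
  if (nMod > 0L) {
    latent <- matrix(rnorm(nMod * nSamp), nMod, nSamp,
                     dimnames = list(paste0("M", seq_len(nMod)),
                                     samples$sample_id))
    offset <- 0L
    for (m in seq_len(nMod)) {
      idx <- offset + seq_len(config@moduleSizes[m])
      moduleAssign[idx] <- m
      offset <- offset + config@moduleSizes[m]
    }
  }
  lam <- sqrt(config@moduleCor)
  stoch <- matrix(rnorm(config@nGenes * nSamp), config@nGenes, nSamp)
  inMod <- moduleAssign > 0L
  if (any(inMod)) {
    stoch[inMod, ] <- lam * latent[moduleAssign[inMod], , drop = FALSE] +
      sqrt(1 - config@moduleCor) * stoch[inMod, , drop = FALSE]
  }
  Y <- Y + config@noiseSd * stoch

  # planted DE: EW samples of designated groups shifted on non-module genes
  deGenes <- character()
  if (config@nDEGenes > 0L) {
    pool <- genes[!inMod]
    if (length(pool) < config@nDEGenes)
      stop("not enough non-module genes to plant DE effects")
    deGenes <- sort(sample(pool, config@nDEGenes))
    hit <- samples$stimulation == "EW" & samples$group %in% config@deGroups
    Y[deGenes, hit] <- Y[deGenes, hit] + config@deLog2FC
  }

  # covariate offsets (subject-level, shared by both samples of a subject)
  batchEff <- setNames(rnorm(5L, sd = 0.2), paste0("B", 1:5))
  genderGenes <- sample(genes, max(1L, round(0.05 * config@nGenes)))
  Y <- sweep(Y, 2L, batchEff[samples$batch], "+")
  Y[genderGenes, samples$gender == "F"] <-
    Y[genderGenes, samples$gender == "F"] + 0.3

  exp <- StimExperiment(Y, samples)
  deContrasts <- c(paste0("EWvsM_", config@deGroups),
                   paste0("dd_", setdiff(config@deGroups, "AC"), "vsAC"))
  truth <- list(de_genes = deGenes,
                de_contrasts = deContrasts,
                module_assignment = moduleAssign,
                latent_factors = latent)
  list(experiment = exp, truth = truth)
}

#' Simulate an immunologic signature collection with a planted category
#'
#' Builds \code{nSignatures} gene sets over the simulated gene universe and a
#' 4-level \linkS4class{AnnotationMap}. Signatures assigned to
#' \code{plantedCategory} draw \code{plantedOverlap} of their members from the
#' planted DE genes (hence are hypergeometrically enriched in a true-positive
#' DEG signature); all other signatures are uniform draws from the universe.
#' The planted signatures stay grouped under the planted category at every
#' level; remaining signatures are partitioned at random, with more, finer
#' categories at higher levels.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param truth ground-truth list from [simulateExpression()] (uses
#'   \code{de_genes}).
#' @param universe character vector of gene ids (the simulated gene space).
#' @return list with elements \code{collection}
#'   (\linkS4class{GeneSetCollection}) and \code{annotation}
#'   (\linkS4class{AnnotationMap}).
#' @export
simulateGeneSets <- function(config, truth, universe) {
  methods::validObject(config)
  set.seed(config@seed + 1000L)
  nSig <- config@nSignatures
  nCat <- config@nCategories
  sigSize <- config@signatureSize
  if (sigSize > length(universe))
    stop("signatureSize exceeds the gene universe")
  nPlantedMembers <- round(config@plantedOverlap * sigSize)
  if (nPlantedMembers > length(truth$de_genes))
    stop("plantedOverlap requests more planted-overlap genes than exist")

  perCat <- nSig %/% nCat
  if (perCat < 1L) stop("need at least one signature per category")
  catOf <- rep(seq_len(nCat), length.out = nSig)
  catNames <- sprintf("C%02d", seq_len(nCat))
  if (!config@plantedCategory %in% catNames)
    stop("plantedCategory must be one of ", paste(catNames, collapse = ", "))
  sigNames <- sprintf("SIG%03d", seq_len(nSig))
  plantedIdx <- which(catNames[catOf] == config@plantedCategory)

  sets <- vector("list", nSig)
  names(sets) <- sigNames
  for (i in seq_len(nSig)) {
    if (i %in% plantedIdx && nPlantedMembers > 0L) {
      core <- sample(truth$de_genes, nPlantedMembers)
      rest <- sample(setdiff(universe, core), sigSize - nPlantedMembers)
      sets[[i]] <- sort(c(core, rest))
    } else {
      sets[[i]] <- sort(sample(universe, sigSize))
    }
  }
  collection <- geneSets(sets, name = "synthetic_immune", source = "C7")

  # 4 annotation levels: planted signatures co-travel; others re-partitioned
  assign <- list()
  levelCats <- pmin(c(nCat, nCat * 2L, nCat * 2L, max(2L, nCat %/% 2L)),
                    nSig)
  for (lv in 1:4) {
    if (lv == 1L) {
      cats <- catNames[catOf]
    } else {
      cats <- sprintf("L%d_C%02d",
                      lv, sample(seq_len(levelCats[lv]), nSig, replace = TRUE))
      cats[plantedIdx] <- config@plantedCategory
    }
    assign[[lv]] <- data.frame(level = lv, signature = sigNames,
                               category = cats, stringsAsFactors = FALSE)
  }
  annotation <- annotationMap(do.call(rbind, assign))
  list(collection = collection, annotation = annotation,
       planted_signatures = sigNames[plantedIdx])
}

#' Simulate a multiplex cytokine table
#'
#' Per-subject media (M) and stimulated (EW) concentrations in pg/ml for each
#' cytokine in \code{cytokineEffects}. Baselines and responses are generated
#' on the log10 scale; EW values receive the per-group shifts from
#' \code{cytokineEffects}; all concentrations below the detection floor are
#' clamped to the floor (imitating a multiplex assay's lower limit of
#' quantitation).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return long-format data.frame with columns \code{subject_id},
#'   \code{group}, \code{cytokine}, \code{condition}, \code{concentration}.
#' @export
simulateCytokines <- function(config) {
  methods::validObject(config)
  set.seed(config@seed + 2000L)
  subj <- .subjectTable(config)
  cyts <- names(config@cytokineEffects)
  out <- vector("list", length(cyts))
  for (j in seq_along(cyts)) {
    eff <- config@cytokineEffects[[j]]
    shift <- rep(0, nrow(subj))
    if (length(eff)) {
      hit <- subj$group %in% names(eff)
      shift[hit] <- eff[subj$group[hit]]
    }
    # media baseline around 1-10 pg/ml; EW adds a mild universal response
    logM <- rnorm(nrow(subj), mean = 0.5, sd = config@cytokineNoiseSd)
    logEW <- logM + 0.2 + shift + rnorm(nrow(subj), sd = config@cytokineNoiseSd)
    m <- 10^logM
    ew <- 10^logEW
    if (any(ew < 0) || any(m < 0))
      warning("negative concentrations clamped to zero")
    out[[j]] <- data.frame(
      subject_id = rep(subj$subject_id, 2L),
      group = rep(subj$group, 2L),
      cytokine = cyts[j],
      condition = rep(c("M", "EW"), each = nrow(subj)),
      concentration = pmax(c(m, ew), config@detectionFloor),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate the complete study
#'
#' Convenience wrapper running [simulateExpression()], [simulateGeneSets()]
#' and [simulateCytokines()] from one config.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{experiment}, \code{truth}, \code{collection},
#'   \code{annotation}, \code{planted_signatures}, \code{cytokines}.
#' @export
simulateStudy <- function(config) {
  ex <- simulateExpression(config)
  gs <- simulateGeneSets(config, ex$truth, rownames(ex$experiment))
  cy <- simulateCytokines(config)
  list(experiment = ex$experiment, truth = ex$truth,
       collection = gs$collection, annotation = gs$annotation,
       planted_signatures = gs$planted_signatures, cytokines = cy)
}
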