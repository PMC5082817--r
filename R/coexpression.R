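#' Soft-thresholded co-expression adjacency
#'
#' Unsigned weighted-network adjacency: \eqn{a_{ij} = |cor(x_i, x_j)|^\beta}
#' with unit diagonal. Zero-variance genes are removed (count reported via
#' message).
#'
#' @param exprs numeric matrix, genes x samples (>= 3 samples).
#' @param beta soft-thresholding power, default 7.
#' @return symmetric gene x gene adjacency matrix in [0, 1].
#' @export
softAdjacency <- function(exprs, beta = 7) {
  if (beta <= 0) stop("beta must be positive")
  if (ncol(exprs) < 3L) stop("need >= 3 samples")
  v <- apply(exprs, 1L, var)
  if (any(v == 0)) {
    message(sum(v == 0), " zero-variance gene(s) removed")
    exprs <- exprs[v > 0, , drop = FALSE]
  }
  a <- abs(cor(t(exprs)))^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' Unsigned TOM similarity: for genes i and j,
#' \deqn{TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
#'                       {\min(k_i, k_j) + 1 - a_{ij}}}
#' with \eqn{k_i = \sum_{u \ne i} a_{iu}} (connectivity) and
#' \eqn{TOM_{ii} = 1}. Genes sharing many strong neighbours score high even
#' when their direct adjacency is moderate.
#'
#' @param adjacency symmetric adjacency matrix with unit diagonal.
#' @return symmetric TOM similarity matrix in [0, 1].
#' @export
topologicalOverlap <- function(adjacency) {
  if (max(abs(adjacency - t(adjacency))) > 1e-10)
    stop("adjacency must be symmetric")
  if (max(abs(diag(adjacency) - 1)) > 1e-10)
    stop("adjacency must have unit diagonal")
  k <- rowSums(adjacency) - 1
  L <- adjacency %*% adjacency
  # remove u = i and u = j terms from the path sum (diag is 1)
  num <- L - 2 * adjacency + adjacency
  den <- outer(k, k, pmin) + 1 - adjacency
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  (tom + t(tom)) / 2
}

#' Detect co-expression modules by hierarchical clustering
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity
#' (1 - TOM), cut at a fixed height (default 0.85 x the tallest merge:
#' unconnected background genes join the tree only in the topmost stretch of
#' merge heights while within-module joins complete well below it, so this
#' cut leaves background unassigned without splitting co-expressed blocks).
#' Clusters of at least \code{minModuleSize}
#' genes become modules, numbered in decreasing size order; all other genes
#' get label 0 (unassigned).
#'
#' @param dissimilarity square dissimilarity matrix (e.g. \code{1 - TOM}),
#'   with gene ids as dimnames.
#' @param minModuleSize smallest admissible module, default 50 genes.
#' @param cutHeight tree cut height; \code{NULL} means
#'   \code{0.85 * max(merge height)}.
#' @return a \linkS4class{ModulePartition}.
#' @export
detectModules <- function(dissimilarity, minModuleSize = 50L,
                          cutHeight = NULL) {
  if (nrow(dissimilarity) != ncol(dissimilarity))
    stop("dissimilarity must be square")
  genes <- rownames(dissimilarity)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(dissimilarity)))
  hc <- hclust(as.dist(dissimilarity), method = "average")
  if (is.null(cutHeight)) cutHeight <- 0.85 * max(hc$height)
  cl <- cutree(hc, h = cutHeight)
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= minModuleSize])
  lab <- ifelse(cl %in% keep, cl, 0L)
  if (all(lab == 0L)) warning("no cluster reaches minModuleSize; ",
                              "all genes unassigned")
  modulePartition(setNames(as.integer(lab), genes))
}

#' Module eigengene
#'
#' The module's summary profile: first principal component of the per-gene
#' z-scored member submatrix, normalized to unit length over samples, and
#' sign-oriented so its mean correlation with member genes is non-negative
#' (an orientation convention — individual members may still anti-correlate).
#' Zero-variance members are dropped from the computation.
#'
#' @param exprs numeric matrix, genes x samples.
#' @param partition a \linkS4class{ModulePartition}.
#' @param module module label.
#' @return numeric vector over samples (unit norm).
#' @export
moduleEigengene <- function(exprs, partition, module) {
  genes <- intersect(moduleGenes(partition, module), rownames(exprs))
  if (length(genes) < 2L) stop("module must contain >= 2 genes")
  sub <- exprs[genes, , drop = FALSE]
  v <- apply(sub, 1L, var)
  if (any(v == 0)) {
    message(sum(v == 0), " zero-variance member(s) dropped from eigengene")
    sub <- sub[v > 0, , drop = FALSE]
  }
  z <- t(scale(t(sub)))
  sv <- svd(z, nu = 0L, nv = 1L)
  eg <- sv$v[, 1L]
  if (mean(cor(eg, t(sub))) < 0) eg <- -eg
  setNames(eg, colnames(exprs))
}

#' Eigengenes of all modules
#'
#' @param exprs numeric matrix, genes x samples.
#' @param partition a \linkS4class{ModulePartition}.
#' @return numeric matrix, modules x samples; rownames are module labels.
#' @export
moduleEigengenes <- function(exprs, partition) {
  labs <- as.integer(names(moduleSizes(partition)))
  me <- t(vapply(labs, function(m) moduleEigengene(exprs, partition, m),
                 numeric(ncol(exprs))))
  dimnames(me) <- list(as.character(labs), colnames(exprs))
  me
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the module pair whose eigengene dissimilarity
#' (1 - Pearson correlation) is smallest, while that dissimilarity is below
#' \code{cutoff}; eigengenes are recomputed after every merge. Final labels
#' are renumbered by decreasing size.
#'
#' @param exprs numeric matrix, genes x samples.
#' @param partition a \linkS4class{ModulePartition}.
#' @param cutoff eigengene dissimilarity below which modules merge,
#'   default 0.29.
#' @return a \linkS4class{ModulePartition}.
#' @export
mergeModules <- function(exprs, partition, cutoff = 0.29) {
  assign <- moduleAssignment(partition)
  repeat {
    labs <- as.integer(names(table(assign[assign > 0L])))
    if (length(labs) < 2L) break
    part <- modulePartition(assign)
    assign <- moduleAssignment(part)
    me <- moduleEigengenes(exprs, part)
    diss <- 1 - cor(t(me))
    diag(diss) <- Inf
    mn <- which(diss == min(diss), arr.ind = TRUE)[1L, ]
    if (diss[mn[1L], mn[2L]] >= cutoff) break
    from <- as.integer(rownames(me)[max(mn)])
    to <- as.integer(rownames(me)[min(mn)])
    assign[assign == from] <- to
  }
  modulePartition(assign)
}

#' Module-trait association by linear regression
#'
#' Per (module, trait) pair, simple linear regression of the trait on the
#' module eigengene; Benjamini-Hochberg across all pairs. Samples with
#' missing trait values are dropped pairwise; a constant trait yields p = 1
#' (with a warning).
#'
#' @param eigengenes numeric matrix, modules x samples (from
#'   [moduleEigengenes()]).
#' @param traits data.frame or matrix of numeric traits, one row per sample
#'   of \code{eigengenes} (rownames matched to its colnames when present).
#' @return data.frame with \code{module}, \code{trait}, \code{slope},
#'   \code{r}, \code{p_value}, \code{fdr_p}.
#' @export
moduleTraitAssociation <- function(eigengenes, traits) {
  traits <- as.data.frame(traits)
  if (!is.null(rownames(traits)) &&
      all(colnames(eigengenes) %in% rownames(traits)))
    traits <- traits[colnames(eigengenes), , drop = FALSE]
  if (nrow(traits) != ncol(eigengenes))
    stop("traits must have one row per eigengene sample")
  rows <- list()
  for (m in rownames(eigengenes)) {
    for (tr in colnames(traits)) {
      x <- eigengenes[m, ]
      y <- traits[[tr]]
      ok <- is.finite(x) & is.finite(y)
      x <- x[ok]; y <- y[ok]
      if (length(x) < 3L || sd(y) == 0 || sd(x) == 0) {
        if (length(x) >= 3L && sd(y) == 0)
          warning("constant trait '", tr, "': p set to 1")
        rows[[length(rows) + 1L]] <-
          data.frame(module = as.integer(m), trait = tr, slope = 0,
                     r = 0, p_value = 1, stringsAsFactors = FALSE)
        next
      }
      fit <- summary(lm(y ~ x))
      rows[[length(rows) + 1L]] <-
        data.frame(module = as.integer(m), trait = tr,
                   slope = fit$coefficients["x", "Estimate"],
                   r = cor(x, y),
                   p_value = fit$coefficients["x", "Pr(>|t|)"],
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr_p <- benjaminiHochberg(pmax(out$p_value, .Machine$double.xmin))
  rownames(out) <- NULL
  out
}

#' Per-subject eigengene stimulation deltas
#'
#' Aligns eigengenes to subject-level traits (e.g. cytokine deltas): for each
#' subject with both an EW and an M sample, the EW - M difference of each
#' module eigengene.
#'
#' @param eigengenes modules x samples matrix.
#' @param samples sample metadata data.frame (needs \code{sample_id},
#'   \code{subject_id}, \code{stimulation}).
#' @return modules x subjects matrix of eigengene deltas.
#' @export
eigengeneDeltas <- function(eigengenes, samples) {
  ew <- samples[samples$stimulation == "EW", ]
  m <- samples[samples$stimulation == "M", ]
  subj <- intersect(ew$subject_id, m$subject_id)
  ewId <- ew$sample_id[match(subj, ew$subject_id)]
  mId <- m$sample_id[match(subj, m$subject_id)]
  d <- eigengenes[, ewId, drop = FALSE] - eigengenes[, mId, drop = FALSE]
  colnames(d) <- subj
  d
}
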