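#' Filter probes by detection rate
#'
#' Retains probes whose signal was above background in at least
#' \code{minFraction} of samples (the complement of the array-QC rule that
#' discards probes detected in fewer than 20 percent of samples; a probe at
#' exactly the boundary is retained).
#'
#' @param probes numeric matrix, probes x samples (log2 scale).
#' @param detected logical matrix conformal with \code{probes}: TRUE where the
#'   probe's signal exceeded background in that sample.
#' @param minFraction minimum detection fraction, default 0.20.
#' @return the filtered probe matrix.
#' @examples
#' p <- matrix(rnorm(20, 8), 2, 10,
#'             dimnames = list(c("p1", "p2"), paste0("s", 1:10)))
#' det <- rbind(rep(TRUE, 10), c(TRUE, rep(FALSE, 9)))
#' nrow(filterProbesByDetection(p, det))  # p2 detected in 1/10 -> dropped
#' @export
filterProbesByDetection <- function(probes, detected, minFraction = 0.20) {
  if (!identical(dim(probes), dim(detected)))
    stop("'detected' must be conformal with 'probes'")
  keep <- rowMeans(detected) >= minFraction
  probes[keep, , drop = FALSE]
}

#' Collapse probes to genes by highest mean expression
#'
#' One row per gene: among a gene's probes, the probe with the highest mean
#' expression across samples represents the gene. Probes without a gene
#' mapping are dropped (count reported via message). Ties in mean expression
#' go to the lexicographically smallest probe id.
#'
#' @param probes numeric matrix, probes x samples; rownames are probe ids.
#' @param probe2gene named character vector probe id -> gene id.
#' @return numeric matrix, genes x samples; rownames are gene ids.
#' @export
collapseProbesToGenes <- function(probes, probe2gene) {
  pid <- rownames(probes)
  mapped <- pid %in% names(probe2gene) & !is.na(probe2gene[pid])
  if (any(!mapped))
    message(sum(!mapped), " unmapped probe(s) dropped")
  probes <- probes[mapped, , drop = FALSE]
  pid <- rownames(probes)
  gene <- as.character(probe2gene[pid])
  m <- rowMeans(probes)
  # order: by gene, then mean desc, then probe id asc -> first row per gene
  ord <- order(gene, -m, pid)
  keep <- ord[!duplicated(gene[ord])]
  out <- probes[keep, , drop = FALSE]
  rownames(out) <- gene[keep]
  out[order(rownames(out)), , drop = FALSE]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wrapper over \code{stats::p.adjust}, validated
#' inputs): adjusted value i is \code{min_{k >= i} m * p_(k) / k} capped at 1.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values in input order; empty input gives empty output.
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
benjaminiHochberg <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

# vectorised per-gene OLS: Y genes x n, X n x p design; returns stats for
# the coefficient named `coefName`. Aliased columns dropped with a warning.
.geneLm <- function(Y, X, coefName) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    if (coefName %in% dropped)
      stop("contrast coefficient is aliased in the design")
    warning("dropping aliased design column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
    qrX <- qr(X)
  }
  n <- nrow(X)
  df <- n - qrX$rank
  if (df <= 0L) stop("zero residual degrees of freedom")
  j <- match(coefName, colnames(X))
  if (is.na(j)) stop("coefficient '", coefName, "' not in design")
  coefs <- t(qr.coef(qrX, t(Y)))          # genes x p
  res <- Y - coefs %*% t(X)
  sigma2 <- rowSums(res^2) / df
  xtxinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * xtxinv[j, j])
  tstat <- coefs[, j] / se
  pval <- 2 * pt(-abs(tstat), df)
  list(coef = coefs[, j], se = se, t = tstat, p = pval, df = df)
}

# per-subject EW - M delta matrix for the given subjects; also returns
# subject-level covariates
.subjectDeltas <- function(exprs, samples, subjects) {
  ew <- samples$sample_id[samples$stimulation == "EW" &
                          samples$subject_id %in% subjects]
  m <- samples$sample_id[samples$stimulation == "M" &
                         samples$subject_id %in% subjects]
  ewSub <- samples$subject_id[match(ew, samples$sample_id)]
  mSub <- samples$subject_id[match(m, samples$sample_id)]
  paired <- intersect(ewSub, mSub)
  dropped <- setdiff(subjects, paired)
  if (length(dropped))
    message(length(dropped), " unpaired subject(s) dropped: ",
            paste(dropped, collapse = ", "))
  ew <- ew[match(paired, ewSub)]
  m <- m[match(paired, mSub)]
  D <- exprs[, ew, drop = FALSE] - exprs[, m, drop = FALSE]
  colnames(D) <- paired
  info <- samples[match(paired, samples$subject_id),
                  c("subject_id", "group", "gender", "batch")]
  rownames(info) <- paired
  list(deltas = D, subjects = info,
       aveExpr = rowMeans(exprs[, c(ew, m), drop = FALSE]))
}

# factor with batch/gender collapsed if constant; returns model matrix
.designWithCovariates <- function(front, info) {
  stopifnot(nrow(front) == nrow(info))
  covs <- NULL
  for (v in c("gender", "batch")) {
    x <- factor(info[[v]])
    if (nlevels(x) > 1L) {
      mm <- model.matrix(~x)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(v, seq_len(ncol(mm)))
      covs <- cbind(covs, mm)
    }
  }
  cbind(front, covs)
}

#' Fit a per-gene linear-model contrast
#'
#' Ordinary least squares per gene, with gender and batch as covariates:
#' \describe{
#'   \item{family 1 (\code{between_group_within_condition})}{samples of the
#'     chosen condition in groups A and B; reported coefficient is the
#'     adjusted group A - group B difference.}
#'   \item{family 2 (\code{within_group_EW_vs_M})}{per-subject paired EW - M
#'     deltas within group A; tests the adjusted mean delta against 0.}
#'   \item{family 3 (\code{difference_of_differences})}{per-subject EW - M
#'     deltas of groups A and B; reported coefficient is the adjusted
#'     between-group difference of deltas (the stimulation-by-group
#'     interaction).}
#' }
#' Two-sided p-values come from the t statistic; \code{fdr_p} is
#' Benjamini-Hochberg over all genes of this contrast.
#'
#' @param experiment a \linkS4class{StimExperiment}.
#' @param contrast a \linkS4class{ContrastSpec}.
#' @return data.frame (DEG table) with columns \code{gene_id}, \code{log2FC},
#'   \code{ave_expr}, \code{t}, \code{p_value}, \code{fdr_p},
#'   \code{contrast_id}; rows sorted by p ascending (ties: larger |log2FC|
#'   first, then gene id).
#' @examples
#' sim <- simulateExpression(simulationConfig(
#'   nSubjects = c(AC = 6, BET = 6, BER = 6), nGenes = 300, nDEGenes = 30,
#'   moduleSizes = integer(), seed = 3))
#' deg <- fitContrast(sim$experiment, contrastSpec("difference_of_differences",
#'                                                 "BER", "AC"))
#' head(deg)
#' @export
fitContrast <- function(experiment, contrast) {
  methods::validObject(contrast)
  exprs <- exprsMatrix(experiment)
  samples <- sampleData(experiment)
  if (is.null(samples$sample_id)) samples$sample_id <- rownames(samples)
  fam <- contrast@family

  if (fam == "between_group_within_condition") {
    sel <- samples$stimulation == contrast@condition &
      samples$group %in% c(contrast@groupA, contrast@groupB)
    info <- samples[sel, ]
    if (min(table(info$group)) < 3L)
      stop("need >= 3 samples per group in the chosen condition")
    Y <- exprs[, info$sample_id, drop = FALSE]
    g <- as.numeric(info$group == contrast@groupA)
    X <- .designWithCovariates(
      cbind(`(Intercept)` = 1, groupA = g), info)
    fit <- .geneLm(Y, X, "groupA")
    aveExpr <- rowMeans(Y)
  } else if (fam == "within_group_EW_vs_M") {
    subjects <- unique(samples$subject_id[samples$group == contrast@groupA])
    d <- .subjectDeltas(exprs, samples, subjects)
    if (ncol(d$deltas) < 3L) stop("need >= 3 paired subjects")
    X <- .designWithCovariates(
      matrix(1, nrow(d$subjects), 1L,
             dimnames = list(NULL, "(Intercept)")), d$subjects)
    fit <- .geneLm(d$deltas, X, "(Intercept)")
    aveExpr <- d$aveExpr
  } else { # difference_of_differences
    subjects <- unique(samples$subject_id[samples$group %in%
                                          c(contrast@groupA, contrast@groupB)])
    d <- .subjectDeltas(exprs, samples, subjects)
    if (min(table(d$subjects$group)) < 3L)
      stop("need >= 3 paired subjects per group")
    g <- as.numeric(d$subjects$group == contrast@groupA)
    X <- .designWithCovariates(
      cbind(`(Intercept)` = 1, groupA = g), d$subjects)
    fit <- .geneLm(d$deltas, X, "groupA")
    aveExpr <- d$aveExpr
  }

  pcl <- pmax(fit$p, .Machine$double.xmin)  # keep p in (0,1] for exact fits
  out <- data.frame(gene_id = rownames(exprs),
                    log2FC = unname(fit$coef),
                    ave_expr = unname(aveExpr),
                    t = unname(fit$t),
                    p_value = unname(pcl),
                    fdr_p = benjaminiHochberg(pcl),
                    contrast_id = contrastId(contrast),
                    stringsAsFactors = FALSE)
  out[order(out$p_value, -abs(out$log2FC), out$gene_id), , drop = FALSE]
}

#' Standardize a DEG signature
#'
#' Because raw DEG lists vary greatly in size across contrasts, signatures
#' are standardized: restrict to genes whose fold-change sign matches
#' \code{direction} (genes at exactly 0 belong to neither), keep the
#' \code{nSignificant} smallest p-values among them, and of those return the
#' \code{nTop} largest absolute fold changes, ordered by |log2FC| descending.
#' Ties break by (p ascending, |log2FC| descending, gene id ascending), so
#' the result is invariant to input row order.
#'
#' @param deg DEG table from [fitContrast()].
#' @param direction \code{"up"} or \code{"down"}.
#' @param nSignificant first-stage cut by p-value, default 500.
#' @param nTop final signature size cap by |fold change|, default 200.
#' @return a \linkS4class{DEGSignature}.
#' @export
standardizeSignature <- function(deg, direction, nSignificant = 500L,
                                 nTop = 200L) {
  stopifnot(direction %in% c("up", "down"))
  keep <- if (direction == "up") deg$log2FC > 0 else deg$log2FC < 0
  d <- deg[keep, , drop = FALSE]
  ord <- order(d$p_value, -abs(d$log2FC), d$gene_id)
  d <- d[head(ord, nSignificant), , drop = FALSE]
  ord2 <- order(-abs(d$log2FC), d$p_value, d$gene_id)
  d <- d[head(ord2, nTop), , drop = FALSE]
  methods::new("DEGSignature",
               contrastId = if (nrow(deg)) deg$contrast_id[1L] else "",
               direction = direction,
               geneIds = d$gene_id)
}
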