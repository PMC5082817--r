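#' First-stage signature enrichment
#'
#' Stage one of the enrichment-of-enrichment procedure: enrich the query
#' against all signatures of the collection that are annotatable at the
#' requested level, and keep those with FDR-adjusted p at or below the
#' threshold (0.01 throughout the analysis by default).
#'
#' @param query a \linkS4class{DEGSignature} or character gene vector.
#' @param collection a \linkS4class{GeneSetCollection} of immunologic
#'   signatures.
#' @param annotation an \linkS4class{AnnotationMap}.
#' @param level annotation level (1-4).
#' @param universe character vector of gene ids.
#' @param fdrThreshold first-stage significance gate on \code{fdr_p}.
#' @return list with \code{results} (full per-signature enrichment table,
#'   restricted to the level's signatures) and \code{enriched} (subset
#'   passing the gate).
#' @export
firstStageEnrichment <- function(query, collection, annotation, level,
                                 universe, fdrThreshold = 0.01) {
  assigned <- names(levelAssignments(annotation, level))
  sets <- setMembers(collection)
  keep <- intersect(names(sets), assigned)
  if (!length(keep))
    stop("no signatures of the collection are annotatable at level ", level)
  sub <- geneSets(sets[keep], name = collection@name,
                  source = collection@source)
  res <- enrichCollection(query, sub, universe)
  list(results = res,
       enriched = res[res$fdr_p <= fdrThreshold, , drop = FALSE])
}

#' Category over-representation test
#'
#' Stage two: is a category over-represented among the significantly
#' enriched signatures? One-sided Fisher exact test on the 2x2 table over
#' all signatures tested at the level (rows: in-category vs not; columns:
#' enriched vs not), i.e. the significantly enriched signatures form the
#' "foreground" against the level's full signature background.
#'
#' @param category category name.
#' @param enrichedSignatures character vector of enriched signature names.
#' @param annotation an \linkS4class{AnnotationMap}.
#' @param level annotation level.
#' @param testedSignatures character vector of all signature names tested at
#'   this level (defaults to every signature annotated at the level).
#' @return one-row data.frame with the table counts, \code{odds_ratio} and
#'   \code{p_value}.
#' @export
categoryTest <- function(category, enrichedSignatures, annotation, level,
                         testedSignatures = NULL) {
  assign <- levelAssignments(annotation, level)
  if (!category %in% assign)
    stop("category '", category, "' absent from level ", level)
  if (is.null(testedSignatures)) testedSignatures <- names(assign)
  inCat <- names(assign)[assign == category]
  inCat <- intersect(inCat, testedSignatures)
  enrichedSignatures <- intersect(enrichedSignatures, testedSignatures)
  fisherEnrichment(enrichedSignatures, inCat, testedSignatures)
}

#' Immune Annotation Score
#'
#' Combined two-stage score for a category:
#' \deqn{score = (-\log_{10} m) \times (-\log_{10} c)}
#' where \eqn{m} is the median first-stage FDR-adjusted p-value over the
#' category's significantly enriched signatures and \eqn{c} is the
#' category-level Fisher p-value. The score is 0 when either input is 1 and
#' grows as both stages strengthen; at the double significance boundary
#' (both p = 0.01) it equals 4.
#'
#' @param medianFdrP median FDR-adjusted p over enriched signatures, in (0,1].
#' @param categoryP category Fisher p-value, in (0,1].
#' @return non-negative numeric score.
#' @examples
#' immuneAnnotationScore(0.01, 0.01)  # 4
#' immuneAnnotationScore(1e-3, 1e-2)  # 6
#' immuneAnnotationScore(1, 1e-8)     # 0
#' @export
immuneAnnotationScore <- function(medianFdrP, categoryP) {
  clamp <- function(p, lab) {
    if (any(p <= 0)) {
      warning(lab, " of 0 clamped to 1e-300")
      p <- pmax(p, 1e-300)
    }
    if (any(p > 1)) stop(lab, " must be <= 1")
    p
  }
  medianFdrP <- clamp(medianFdrP, "medianFdrP")
  categoryP <- clamp(categoryP, "categoryP")
  (-log10(medianFdrP)) * (-log10(categoryP))
}

#' Run one annotation level end-to-end
#'
#' The full enrichment-of-enrichment procedure at one annotation level:
#' first-stage signature enrichment gated at \code{fdrThreshold}; then for
#' every category containing at least one enriched signature, the median of
#' its enriched members' FDR p-values, the category-level Fisher test against
#' the level's signature background, and the Immune Annotation Score.
#' Category p-values are additionally BH-adjusted across the scored
#' categories (\code{category_fdr_p}, usable on its own as the category's
#' enrichment measure). Categories with no enriched signature are not
#' reported.
#'
#' @inheritParams firstStageEnrichment
#' @return data.frame sorted by score descending with columns \code{level},
#'   \code{category}, \code{n_signatures}, \code{n_enriched},
#'   \code{median_fdr_p}, \code{category_p}, \code{category_fdr_p},
#'   \code{odds_ratio}, \code{score}. Zero rows when nothing is enriched.
#' @export
runAnnotationLevel <- function(query, collection, annotation, level,
                               universe, fdrThreshold = 0.01) {
  stage1 <- firstStageEnrichment(query, collection, annotation, level,
                                 universe, fdrThreshold)
  empty <- data.frame(level = integer(), category = character(),
                      n_signatures = integer(), n_enriched = integer(),
                      median_fdr_p = numeric(), category_p = numeric(),
                      category_fdr_p = numeric(), odds_ratio = numeric(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (!nrow(stage1$enriched)) return(empty)
  assign <- levelAssignments(annotation, level)
  tested <- intersect(names(assign), stage1$results$set_name)
  enriched <- stage1$enriched$set_name
  cats <- sort(unique(assign[enriched]))
  rows <- lapply(cats, function(cat) {
    members <- intersect(names(assign)[assign == cat], tested)
    enrIn <- intersect(enriched, members)
    medFdr <- median(stage1$enriched$fdr_p[stage1$enriched$set_name %in%
                                           enrIn])
    ct <- categoryTest(cat, enriched, annotation, level, tested)
    data.frame(level = level, category = cat,
               n_signatures = length(members),
               n_enriched = length(enrIn),
               median_fdr_p = medFdr,
               category_p = ct$p_value,
               odds_ratio = ct$odds_ratio,
               score = immuneAnnotationScore(medFdr,
                                             pmax(ct$p_value,
                                                  .Machine$double.xmin)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$category_fdr_p <- benjaminiHochberg(pmax(out$category_p,
                                               .Machine$double.xmin))
  out <- out[order(-out$score, out$category_p, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("level", "category", "n_signatures", "n_enriched", "median_fdr_p",
          "category_p", "category_fdr_p", "odds_ratio", "score")]
}
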