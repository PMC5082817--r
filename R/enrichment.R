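#' One-sided Fisher exact p-value for set overlap
#'
#' The p-value kernel shared by all enrichment tests in the package: the
#' probability of observing an overlap at least as large as \code{overlap}
#' between a query of \code{querySize} and a target of \code{targetSize}
#' drawn from a universe of \code{universeSize} genes (hypergeometric upper
#' tail). Vectorized over its arguments.
#'
#' @param overlap observed overlap count(s).
#' @param targetSize,querySize,universeSize 2x2 table margins.
#' @return one-sided (greater) p-value(s).
#' @examples
#' fisherTailP(10, 100, 200, 20000)
#' @export
fisherTailP <- function(overlap, targetSize, querySize, universeSize) {
  phyper(overlap - 1, targetSize, universeSize - targetSize, querySize,
         lower.tail = FALSE)
}

#' Fisher exact over-representation of one gene set
#'
#' One-sided (greater) Fisher exact test of the overlap between a query gene
#' list and a target set within a gene universe, i.e. the hypergeometric
#' upper tail of the 2x2 table
#' (query&target, query-only, target-only, neither). Query and target
#' members outside the universe are dropped (count reported via message).
#' The odds ratio is the cross-product ratio with a Haldane correction of
#' 0.5 added to every cell when any cell is zero.
#'
#' @param query character vector of gene ids (e.g. a DEG signature).
#' @param target character vector of gene ids (one gene set).
#' @param universe character vector: the tested gene space.
#' @return one-row data.frame with \code{overlap}, \code{query_size},
#'   \code{target_size}, \code{universe_size}, \code{odds_ratio},
#'   \code{p_value}.
#' @examples
#' fisherEnrichment(paste0("G", 1:10), paste0("G", 6:20), paste0("G", 1:100))
#' @export
fisherEnrichment <- function(query, target, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  target <- unique(target)
  qDrop <- sum(!query %in% universe)
  tDrop <- sum(!target %in% universe)
  if (qDrop + tDrop > 0L)
    message(qDrop, " query and ", tDrop,
            " target gene(s) outside the universe dropped")
  query <- intersect(query, universe)
  target <- intersect(target, universe)
  a <- length(intersect(query, target))
  b <- length(query) - a
  cc <- length(target) - a
  d <- length(universe) - a - b - cc
  p <- fisherTailP(a, length(target), length(query), length(universe))
  cells <- c(a, b, cc, d)
  if (any(cells == 0L)) cells <- cells + 0.5
  or <- (cells[1L] * cells[4L]) / (cells[2L] * cells[3L])
  data.frame(overlap = a, query_size = length(query),
             target_size = length(target),
             universe_size = length(universe),
             odds_ratio = or, p_value = p)
}

#' Enrich a query against a whole collection
#'
#' Runs [fisherEnrichment()] for every set of a
#' \linkS4class{GeneSetCollection} and applies Benjamini-Hochberg across the
#' collection's sets.
#'
#' @param query a \linkS4class{DEGSignature}, or a character vector of gene
#'   ids (e.g. a module's genes).
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param universe character vector of gene ids.
#' @param queryId label recorded in the output (defaults to the signature's
#'   contrast/direction or \code{"query"}).
#' @return data.frame, one row per set, with \code{query_id},
#'   \code{set_name}, overlap geometry, \code{odds_ratio}, \code{p_value},
#'   \code{fdr_p}; row order follows the collection.
#' @export
enrichCollection <- function(query, collection, universe, queryId = NULL) {
  if (methods::is(query, "DEGSignature")) {
    if (is.null(queryId))
      queryId <- paste0(query@contrastId, "_", query@direction)
    query <- signatureGenes(query)
  }
  if (is.null(queryId)) queryId <- "query"
  if (!length(query)) stop("empty query")
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  nU <- length(universe)
  nQ <- length(query)
  sets <- setMembers(collection)
  tSize <- integer(length(sets))
  ov <- integer(length(sets))
  for (i in seq_along(sets)) {
    tg <- sets[[i]][sets[[i]] %in% universe]
    tSize[i] <- length(tg)
    ov[i] <- sum(tg %in% query)
  }
  p <- fisherTailP(ov, tSize, nQ, nU)
  b <- nQ - ov
  cc <- tSize - ov
  d <- nU - ov - b - cc
  or <- numeric(length(sets))
  for (i in seq_along(sets)) {
    cells <- c(ov[i], b[i], cc[i], d[i])
    if (any(cells == 0L)) cells <- cells + 0.5
    or[i] <- (cells[1L] * cells[4L]) / (cells[2L] * cells[3L])
  }
  data.frame(query_id = queryId, set_name = names(sets),
             overlap = ov, query_size = nQ, target_size = tSize,
             universe_size = nU, odds_ratio = or, p_value = p,
             fdr_p = benjaminiHochberg(pmax(p, .Machine$double.xmin)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Module-by-signature enrichment matrix
#'
#' Fisher enrichment of every module's gene list in every DEG signature, with
#' Benjamini-Hochberg applied per signature across modules.
#'
#' @param partition a \linkS4class{ModulePartition}.
#' @param signatures list of \linkS4class{DEGSignature} objects.
#' @param universe character vector of gene ids.
#' @return long data.frame, one row per (module, signature) pair.
#' @export
moduleSignatureEnrichment <- function(partition, signatures, universe) {
  labs <- as.integer(names(moduleSizes(partition)))
  out <- list()
  for (s in seq_along(signatures)) {
    sig <- signatures[[s]]
    sigId <- paste0(sig@contrastId, "_", sig@direction)
    rows <- lapply(labs, function(m) {
      r <- fisherEnrichment(moduleGenes(partition, m), signatureGenes(sig),
                            universe)
      cbind(data.frame(module = m, signature_id = sigId,
                       stringsAsFactors = FALSE), r)
    })
    block <- do.call(rbind, rows)
    block$fdr_p <- benjaminiHochberg(pmax(block$p_value,
                                          .Machine$double.xmin))
    out[[s]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
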