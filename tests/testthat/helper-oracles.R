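# Independent oracles, kept free of the implementation paths they check.

# Direct step-up formula: adjusted_i = min_{k >= rank(i)} m * p_(k) / k,
# capped at 1, mapped back to input order.
bhOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- rev(cummin(rev(m * ps / seq_len(m))))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Upper hypergeometric tail by direct summation of log-binomial terms:
# P(X >= a) for X ~ Hypergeom(target = t of N, draws = q).
hyperTailOracle <- function(a, t, q, N) {
  kmax <- min(q, t)
  if (a > kmax) return(0)
  k <- max(a, max(0L, q + t - N)):kmax
  sum(exp(lchoose(t, k) + lchoose(N - t, q - k) - lchoose(N, q)))
}

# Brute-force TOM by triple loop over intermediate nodes.
tomOracle <- function(adj) {
  n <- nrow(adj)
  k <- rowSums(adj) - 1
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s <- 0
      for (u in seq_len(n))
        if (u != i && u != j) s <- s + adj[i, u] * adj[u, j]
      tom[i, j] <- (s + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
    }
  }
  dimnames(tom) <- dimnames(adj)
  tom
}

# Small paired-design experiment with fully controlled values: one row per
# gene, nSub subjects per group, constant gender/batch so covariates drop.
toyPairedExperiment <- function(deltasByGroup, base = 8) {
  groups <- rep(names(deltasByGroup),
                vapply(deltasByGroup, length, integer(1)))
  nSub <- length(groups)
  subj <- sprintf("S%02d", seq_len(nSub))
  samples <- data.frame(
    sample_id = paste0(rep(subj, each = 2), "_", c("EW", "M")),
    subject_id = rep(subj, each = 2),
    group = rep(groups, each = 2),
    stimulation = rep(c("EW", "M"), nSub),
    gender = "F", batch = "B1", stringsAsFactors = FALSE)
  deltas <- unlist(deltasByGroup, use.names = FALSE)
  m <- matrix(base, 1, nrow(samples),
              dimnames = list("G1", samples$sample_id))
  m[1, samples$stimulation == "EW"] <- base + deltas
  StimExperiment(m, samples)
}

# Compact simulation config for fast unit tests.
smallConfig <- function(seed, ...) {
  args <- list(nSubjects = c(AC = 8L, BET = 10L, BER = 12L),
               nGenes = 500L, nDEGenes = 40L,
               moduleSizes = c(60L, 60L),
               nSignatures = 40L, nCategories = 8L, signatureSize = 40L,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulationConfig, args)
}
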