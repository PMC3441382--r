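# Independent oracles used to cross-check the package implementations.

ch1 <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Exhaustive tiling oracle: minimal cost (unassigned * BIG + mismatches) of
# any motif tiling, by plain recursion over every tiling (no memoization,
# independent of the package DP).
oracle_tiling_cost <- function(domain, lexicon) {
  ch <- ch1(domain)
  n <- length(ch)
  BIG <- n + 1
  mots <- lapply(lexicon$consensus, ch1)
  rec <- function(i) {
    if (i > n) return(0)
    best <- rec(i + 1L) + BIG
    for (r in seq_len(nrow(lexicon))) {
      L <- length(mots[[r]])
      if (i + L - 1L > n) next
      mm <- sum(ch[i:(i + L - 1L)] != mots[[r]])
      if (mm <= lexicon$max_mismatch[r]) best <- min(best, rec(i + L) + mm)
    }
    best
  }
  rec(1L)
}

segmentation_cost <- function(seg) {
  (nchar(seg$domain) + 1) * seg$n_unassigned + seg$total_mismatches
}

# Gotoh three-state affine-gap global alignment score (gap of length k
# costs gap_open + k * gap_extend), written independently of the package's
# alignment route.
oracle_align_score <- function(a, b, p) {
  A <- ch1(a)
  B <- ch1(b)
  n <- length(A)
  m <- length(B)
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in seq_len(n)) {
    X[i + 1L, 1L] <- p$gap_open + i * p$gap_extend
  }
  for (j in seq_len(m)) {
    Y[1L, j + 1L] <- p$gap_open + j * p$gap_extend
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) p$match else p$mismatch
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1L, j + 1L] <- max(
        M[i, j + 1L] + p$gap_open + p$gap_extend,
        Y[i, j + 1L] + p$gap_open + p$gap_extend,
        X[i, j + 1L] + p$gap_extend)
      Y[i + 1L, j + 1L] <- max(
        M[i + 1L, j] + p$gap_open + p$gap_extend,
        X[i + 1L, j] + p$gap_open + p$gap_extend,
        Y[i + 1L, j] + p$gap_extend)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# Least-squares topology oracle for 4 taxa: fit branch lengths to each of
# the three unrooted topologies and return the Newick of the best fit.
oracle_ls_topology4 <- function(D) {
  ids <- rownames(D)
  y <- c(D[1, 2], D[1, 3], D[1, 4], D[2, 3], D[2, 4], D[3, 4])
  # Branch order: a, b, c, d (pendant to taxa 1..4), e (internal).
  designs <- list(
    "12|34" = rbind(c(1, 1, 0, 0, 0), c(1, 0, 1, 0, 1), c(1, 0, 0, 1, 1),
                    c(0, 1, 1, 0, 1), c(0, 1, 0, 1, 1), c(0, 0, 1, 1, 0)),
    "13|24" = rbind(c(1, 1, 0, 0, 1), c(1, 0, 1, 0, 0), c(1, 0, 0, 1, 1),
                    c(0, 1, 1, 0, 1), c(0, 1, 0, 1, 0), c(0, 0, 1, 1, 1)),
    "14|23" = rbind(c(1, 1, 0, 0, 1), c(1, 0, 1, 0, 1), c(1, 0, 0, 1, 0),
                    c(0, 1, 1, 0, 0), c(0, 1, 0, 1, 1), c(0, 0, 1, 1, 1))
  )
  rss <- vapply(designs, function(X) {
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }, 0)
  best <- names(designs)[which.min(rss)]
  nwk <- switch(best,
    "12|34" = sprintf("((%s,%s),(%s,%s));", ids[1], ids[2], ids[3], ids[4]),
    "13|24" = sprintf("((%s,%s),(%s,%s));", ids[1], ids[3], ids[2], ids[4]),
    "14|23" = sprintf("((%s,%s),(%s,%s));", ids[1], ids[4], ids[2], ids[3]))
  ape::read.tree(text = nwk)
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

# Random protein domain over a glutenin-like alphabet.
random_domain <- function(len) {
  paste(sample(c("G", "Q", "P", "Y", "T", "S", "L", "A", "E", "R"), len,
               replace = TRUE,
               prob = c(20, 30, 10, 8, 8, 8, 6, 4, 3, 3)),
        collapse = "")
}

# Annotate a synthetic gene end to end (no warnings expected).
annotate_synthetic <- function(gen) {
  mature <- strip_signal_peptide(translate_orf(gen$record$orf_dna),
                                 id = gen$record$id)
  reference <- strip_signal_peptide(translate_orf(gen$reference$orf_dna),
                                    id = gen$reference$id)
  list(mature = mature, reference = reference,
       partition = partition_domains(mature))
}

# Connected components of a network edge list over the given node ids.
network_components <- function(nodes, edges) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  for (k in seq_len(nrow(edges))) {
    a <- comp[[edges$from[k]]]
    b <- comp[[edges$to[k]]]
    if (a != b) comp[comp == b] <- a
  }
  comp
}
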