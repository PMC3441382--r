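# Median-joining haplotype network (Bandelt-style): minimum-spanning
# network plus inferred median (Steiner) vectors.

# Weighted distance and raw mutation count between two site vectors.
mj_dist <- function(a, b, w) sum(w[a != b])
mj_muts <- function(a, b) sum(a != b)

# Minimum-spanning network over rows of `seqmat` (character matrix, one row
# per node): Kruskal by increasing weighted distance; at each distance
# level, every pair whose endpoints lay in different components *before*
# the level is a feasible link and all feasible links of the level are
# kept. Levels are processed until the graph is connected, then further
# levels within `epsilon` of the connecting level are included as well.
msn_edges <- function(seqmat, w, epsilon = 0) {
  n <- nrow(seqmat)
  if (n == 1L)
    return(data.frame(from = integer(), to = integer(),
                      weight = numeric(), mutations = integer()))
  pairs <- utils::combn(n, 2L)
  dd <- apply(pairs, 2L, function(p) mj_dist(seqmat[p[1], ], seqmat[p[2], ], w))
  comp <- seq_len(n)
  edges <- list()
  connected_at <- NA_real_
  for (lev in sort(unique(dd))) {
    if (!is.na(connected_at) && lev > connected_at + epsilon) break
    at_lev <- which(dd == lev)
    feasible <- at_lev[comp[pairs[1L, at_lev]] != comp[pairs[2L, at_lev]]]
    for (k in feasible) {
      i <- pairs[1L, k]
      j <- pairs[2L, k]
      edges[[length(edges) + 1L]] <- c(i, j, lev)
    }
    for (k in feasible) {
      ci <- comp[pairs[1L, k]]
      cj <- comp[pairs[2L, k]]
      comp[comp == cj] <- ci
    }
    if (is.na(connected_at) && length(unique(comp)) == 1L)
      connected_at <- lev
  }
  if (length(unique(comp)) != 1L)
    stop("minimum-spanning network construction failed to connect")
  e <- do.call(rbind, edges)
  data.frame(
    from = as.integer(e[, 1L]), to = as.integer(e[, 2L]), weight = e[, 3L],
    mutations = vapply(seq_len(nrow(e)), function(r)
      mj_muts(seqmat[e[r, 1L], ], seqmat[e[r, 2L], ]), 0L)
  )
}

# Per-site majority vector of three sequences; a three-way split keeps the
# base of the first sequence (the shared node of the generating edge pair),
# making median construction deterministic.
median_vector <- function(a, b, c) {
  out <- a
  for (s in seq_along(a)) {
    if (b[s] == c[s]) out[s] <- b[s]  # covers b==c (majority) incl. a==b==c
  }
  out
}

#' Median-joining haplotype network
#'
#' Builds a haplotype network in the median-joining family: identical
#' haplotypes are condensed, invariant sites dropped, and a
#' minimum-spanning network (MSN) is computed over the observed haplotypes;
#' median (Steiner) vectors of node triples adjacent in the network are
#' then added one at a time whenever they strictly shorten the MSN, until
#' no candidate improves it; obsolete medians are pruned. All observed
#' haplotypes are retained as nodes and the result is connected. `epsilon`
#' relaxes the MSN feasibility criterion (in weighted-distance units);
#' `weights` is the per-site weight (scalar, uniform; the conventional
#' default is 10).
#'
#' @param haplotypes Named character vector of equal-length aligned DNA
#'   strings.
#' @param epsilon Non-negative tolerance; 0 is the strict default.
#' @param weights Scalar site weight, or vector over alignment sites.
#' @return A `haplotype_network`: `nodes` (data frame: `id`, `type`
#'   observed/median, `sequence` over variable sites, `members` of
#'   condensed identical haplotypes), `edges` (data frame: `from`, `to` node
#'   ids, `mutations`, `weight`), `variable_sites` (1-based alignment
#'   positions) and `parameters`.
#' @export
median_joining_network <- function(haplotypes, epsilon = 0, weights = 10) {
  stopifnot(length(haplotypes) >= 1L, epsilon >= 0)
  ids <- names(haplotypes)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    stop("haplotypes must carry unique names")
  lens <- nchar(haplotypes)
  if (length(unique(lens)) != 1L) stop("haplotypes differ in length")
  full <- do.call(rbind, lapply(haplotypes, chars))
  var_sites <- which(apply(full, 2L, function(col) length(unique(col)) > 1L))
  w <- if (length(weights) == 1L) rep(weights, length(var_sites))
       else weights[var_sites]
  # Condense identical haplotypes.
  key <- apply(full[, var_sites, drop = FALSE], 1L, collapse)
  uniq <- !duplicated(key)
  members <- vapply(key[uniq], function(k)
    paste(ids[key == k], collapse = ","), "")
  seqmat <- full[uniq, var_sites, drop = FALSE]
  node_id <- ids[uniq]
  node_type <- rep("observed", sum(uniq))
  if (nrow(seqmat) == 1L) {
    return(structure(list(
      nodes = data.frame(id = node_id, type = node_type,
                         sequence = key[uniq], members = unname(members),
                         stringsAsFactors = FALSE),
      edges = data.frame(from = character(), to = character(),
                         mutations = integer(), weight = numeric()),
      variable_sites = var_sites,
      parameters = list(epsilon = epsilon, weights = weights)
    ), class = "haplotype_network"))
  }
  total_weight <- function(sm) sum(msn_edges(sm, w, epsilon)$weight)
  n_medians <- 0L
  max_medians <- 2L * nrow(seqmat) + 20L
  repeat {
    edges <- msn_edges(seqmat, w, epsilon)
    current <- sum(edges$weight)
    # Candidate medians from pairs of edges sharing a node (u - v - x).
    cand <- list()
    for (v in seq_len(nrow(seqmat))) {
      nb <- sort(unique(c(edges$to[edges$from == v],
                          edges$from[edges$to == v])))
      if (length(nb) < 2L) next
      for (pq in utils::combn(length(nb), 2L, simplify = FALSE)) {
        m <- median_vector(seqmat[v, ], seqmat[nb[pq[1]], ],
                           seqmat[nb[pq[2]], ])
        cand[[length(cand) + 1L]] <- m
      }
    }
    if (!length(cand)) break
    cand_key <- vapply(cand, collapse, "")
    keep <- !duplicated(cand_key) &
      !(cand_key %in% apply(seqmat, 1L, collapse))
    cand <- cand[keep]
    cand_key <- cand_key[keep]
    if (!length(cand)) break
    gains <- vapply(seq_along(cand), function(k)
      total_weight(rbind(seqmat, cand[[k]])), 0)
    best <- which(gains == min(gains))
    # Deterministic tie-break: lexicographically smallest sequence.
    best <- best[order(cand_key[best])][1L]
    if (gains[best] >= current || n_medians >= max_medians) break
    n_medians <- n_medians + 1L
    seqmat <- rbind(seqmat, cand[[best]])
    node_id <- c(node_id, sprintf("mv%d", n_medians))
    node_type <- c(node_type, "median")
    members <- c(members, "")
  }
  # Prune medians whose removal does not lengthen the network.
  repeat {
    dropped <- FALSE
    for (k in rev(which(node_type == "median"))) {
      sm <- seqmat[-k, , drop = FALSE]
      if (total_weight(sm) <= total_weight(seqmat)) {
        seqmat <- sm
        node_id <- node_id[-k]
        node_type <- node_type[-k]
        members <- members[-k]
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  edges <- msn_edges(seqmat, w, epsilon)
  structure(list(
    nodes = data.frame(id = node_id, type = node_type,
                       sequence = apply(seqmat, 1L, collapse),
                       members = unname(members), stringsAsFactors = FALSE),
    edges = data.frame(from = node_id[edges$from], to = node_id[edges$to],
                       mutations = edges$mutations, weight = edges$weight,
                       stringsAsFactors = FALSE),
    variable_sites = var_sites,
    parameters = list(epsilon = epsilon, weights = weights)
  ), class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("<haplotype_network> ", sum(x$nodes$type == "observed"),
      " observed haplotype(s), ", sum(x$nodes$type == "median"),
      " median vector(s), ", nrow(x$edges), " edge(s) over ",
      length(x$variable_sites), " variable site(s)\n", sep = "")
  invisible(x)
}

#' Write a haplotype network as edge list + node table
#'
#' Two TSV files: `<path>` with columns `from`, `to`, `mutations` and
#' `<path>.nodes.tsv` with the node table; headers record epsilon and
#' weights.
#'
#' @param network A [median_joining_network()] result.
#' @param path Output path for the edge list.
#' @export
write_network <- function(network, path) {
  meta <- sprintf("epsilon=%g; weights=%s",
                  network$parameters$epsilon,
                  paste(unique(network$parameters$weights), collapse = ","))
  write_report(network$edges, path, format = "tsv", metadata = meta)
  write_report(network$nodes, paste0(path, ".nodes.tsv"), format = "tsv",
               metadata = meta)
  invisible(path)
}
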