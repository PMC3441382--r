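# Phylogeny of the conserved region: promoter + signal-peptide CDS +
# N-terminal CDS; p-distances, neighbor joining with bootstrap.

#' Extract the conserved region used for phylogeny
#'
#' HMW-GS phylogeny is built from the conserved parts of each gene: the 5'
#' flanking promoter, plus the coding sequence for the signal peptide and
#' the N-terminal domain, concatenated in that order (the repetitive domain
#' is too labile to align). When the promoter is missing the region is built
#' from the CDS parts only and flagged.
#'
#' @param gene A [gene_record()].
#' @param mature The gene's [strip_signal_peptide()] result.
#' @param partition The gene's [partition_domains()] result.
#' @return A `phylo_region`: `id`, `sequence`, `promoter_included`,
#'   `parts` (component lengths in bp).
#' @export
extract_phylo_region <- function(gene, mature, partition) {
  sig_aa <- nchar(mature$signal_peptide)
  nterm_aa <- span_len(partition$n_terminal)
  cds_len <- 3L * (sig_aa + nterm_aa)
  cds <- substr(gene$orf_dna, 1L, cds_len)
  has_prom <- !is.null(gene$promoter_dna)
  if (!has_prom)
    warning("record '", gene$id, "' has no promoter; phylo region built ",
            "from CDS parts only")
  prom <- if (has_prom) gene$promoter_dna else ""
  structure(list(
    id = gene$id,
    sequence = paste0(prom, cds),
    promoter_included = has_prom,
    parts = c(promoter = nchar(prom), signal_cds = 3L * sig_aa,
              nterm_cds = 3L * nterm_aa)
  ), class = "phylo_region")
}

#' Pairwise p-distance matrix with pairwise deletion
#'
#' Proportion of differing sites per sequence pair, counted over the sites
#' where neither sequence has a gap or ambiguity (gaps treated as missing
#' data, pairwise deletion).
#'
#' @param aligned Named character vector of equal-length aligned DNA
#'   strings (>= 2 sequences).
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
p_distance_matrix <- function(aligned) {
  n <- length(aligned)
  stopifnot(n >= 2L)
  ids <- names(aligned)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    stop("aligned sequences must carry unique names")
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences differ in length")
  m <- do.call(rbind, lapply(aligned, chars))
  valid <- m == "A" | m == "C" | m == "G" | m == "T"
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- valid[i, ] & valid[j, ]
      if (!any(ok))
        stop("no comparable sites between '", ids[i], "' and '", ids[j], "'")
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    }
  }
  d
}

# Clamp negative NJ branch lengths to zero, transferring the (negative)
# remainder to an adjacent branch so path lengths are approximately
# preserved: the sibling branch at the same internal node when one exists,
# otherwise the branch above it. Deterministic by edge index.
clamp_negative_edges <- function(tree) {
  for (i in which(tree$edge.length < 0)) {
    parent <- tree$edge[i, 1L]
    take <- tree$edge.length[i]
    tree$edge.length[i] <- 0
    adj <- setdiff(which(tree$edge[, 1L] == parent |
                           tree$edge[, 2L] == parent), i)
    if (length(adj))
      tree$edge.length[adj[1L]] <- tree$edge.length[adj[1L]] + take
  }
  # Any residue that could not be absorbed is clamped outright.
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix (via `ape::nj`), with
#' rows/columns ordered lexicographically by id for deterministic output and
#' negative branch lengths clamped to zero (remainder transferred to the
#' adjacent branch).
#'
#' @param D Symmetric distance matrix with dimnames (see
#'   [p_distance_matrix()]).
#' @return An `ape::phylo` tree. For n < 3 a trivial tree is returned with
#'   a warning.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), !is.null(rownames(D)),
            identical(rownames(D), colnames(D)))
  ids <- sort(rownames(D))
  D <- D[ids, ids, drop = FALSE]
  n <- length(ids)
  if (n < 3L) {
    warning("fewer than 3 taxa; returning trivial tree")
    tree <- list(edge = cbind(rep(n + 1L, n), seq_len(n)),
                 edge.length = if (n == 2L) rep(D[1, 2] / 2, 2) else 0,
                 tip.label = ids, Nnode = 1L)
    class(tree) <- "phylo"
    return(tree)
  }
  clamp_negative_edges(ape::nj(D))
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' sites with replacement `n_reps` times; the support of each internal edge
#' is the percentage of replicate NJ trees containing the same bipartition.
#' Deterministic given `seed`.
#'
#' @param aligned Named character vector of equal-length aligned DNA
#'   strings.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer RNG seed (recorded on the output).
#' @return The NJ `phylo` tree with `node.label` holding bootstrap
#'   percentages (root label empty) and attributes `seed` and `n_reps`.
#' @export
bootstrap_support <- function(aligned, n_reps = 1000L, seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  main <- neighbor_joining(p_distance_matrix(aligned))
  mat <- do.call(rbind, lapply(aligned, chars))
  n_sites <- ncol(mat)
  reps <- with_seed(seed, lapply(seq_len(n_reps), function(i) {
    idx <- sample.int(n_sites, n_sites, replace = TRUE)
    res <- apply(mat[, idx, drop = FALSE], 1L, collapse)
    names(res) <- rownames(mat)
    tryCatch(neighbor_joining(p_distance_matrix(res)),
             error = function(e) NULL)
  }))
  reps <- Filter(Negate(is.null), reps)
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / length(reps), 1)
  main$node.label <- as.character(support)
  main$node.label[1L] <- ""  # root of the unrooted representation
  attr(main, "seed") <- seed
  attr(main, "n_reps") <- n_reps
  main
}

#' Write a tree as Newick
#'
#' Bootstrap supports, when present, are written as internal node labels.
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
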