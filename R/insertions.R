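# Detection of large inserted blocks relative to a reference subunit and
# verification of their tandem-duplication origin.

#' Default alignment parameters
#'
#' Long-gap-friendly affine scores so that a single block duplication of
#' 100+ residues aligns as one contiguous gap rather than scattered gaps:
#' match +2, mismatch -1, gap open -10, gap extend -0.2 per residue.
#'
#' @return Named list of alignment parameters.
#' @export
default_align_params <- function() {
  list(match = 2, mismatch = -1, gap_open = -10, gap_extend = -0.2)
}

# Full-alphabet substitution matrix for simple match/mismatch scoring.
aa_score_matrix <- function(match, mismatch) {
  ab <- c(LETTERS, "*")
  m <- matrix(mismatch, length(ab), length(ab), dimnames = list(ab, ab))
  diag(m) <- match
  m
}

#' Global pairwise alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties
#' (gap cost = `gap_open + k * gap_extend` for a k-residue gap), via
#' `Biostrings::pairwiseAlignment()`.
#'
#' @param query,ref Protein strings.
#' @param params Scoring parameters, see [default_align_params()].
#' @return An `alignment_result`: `aligned_query`, `aligned_ref` (gapped,
#'   equal length), `score`, `params`. Degapping the aligned strings always
#'   reconstructs the inputs.
#' @export
global_align <- function(query, ref, params = default_align_params()) {
  stopifnot(nzchar(query), nzchar(ref))
  mat <- aa_score_matrix(params$match, params$mismatch)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(ref),
    substitutionMatrix = mat,
    gapOpening = abs(params$gap_open), gapExtension = abs(params$gap_extend),
    type = "global"
  )
  aq <- as.character(Biostrings::alignedPattern(pa))
  ar <- as.character(Biostrings::alignedSubject(pa))
  stopifnot(gsub("-", "", aq, fixed = TRUE) == query,
            gsub("-", "", ar, fixed = TRUE) == ref)
  structure(list(aligned_query = unname(aq), aligned_ref = unname(ar),
                 score = Biostrings::score(pa), params = params),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment_result> ", nchar(x$aligned_query), " columns, score ",
      format(x$score), "\n", sep = "")
  invisible(x)
}

# Canonicalize an insertion block [s, e] of query q. The gap placement of a
# tandem duplication is alignment-ambiguous: the block can slide left while
# q[s-1] == q[e] and right while q[e+1] == q[s] without changing the
# alignment score. Among these equivalent placements we pick the one whose
# fragment parses best against the motif lexicon (fewest unassigned
# residues, then fewest token mismatches), breaking ties leftmost -- for a
# duplication planted at repeat-token boundaries this recovers the copy
# exactly.
canonicalize_block <- function(q, s, e, lexicon) {
  n <- nchar(q)
  spans <- list(c(s, e))
  s2 <- s; e2 <- e
  while (s2 > 1L && substr(q, s2 - 1L, s2 - 1L) == substr(q, e2, e2)) {
    s2 <- s2 - 1L; e2 <- e2 - 1L
    spans[[length(spans) + 1L]] <- c(s2, e2)
  }
  s2 <- s; e2 <- e
  while (e2 < n && substr(q, e2 + 1L, e2 + 1L) == substr(q, s2, s2)) {
    s2 <- s2 + 1L; e2 <- e2 + 1L
    spans[[length(spans) + 1L]] <- c(s2, e2)
  }
  if (length(spans) == 1L) return(spans[[1L]])
  L <- e - s + 1L
  cost <- vapply(spans, function(sp) {
    seg <- segment_repeats(substr(q, sp[1], sp[2]), lexicon)
    seg$n_unassigned * (L + 1) + seg$total_mismatches
  }, 0)
  starts <- vapply(spans, `[`, 0L, 1L)
  best <- which(cost == min(cost))
  spans[[best[order(starts[best])][1L]]]
}

#' Detect large inserted blocks relative to a reference subunit
#'
#' Globally aligns the query and reference mature subunits (same subunit
#' type required) and reports every maximal run of reference gaps of at
#' least `min_block` residues as an insertion block. Blocks are
#' left-normalized (slid to their leftmost equivalent placement) and each
#' receives a motif census of the inserted fragment. The default
#' `min_block = 30` separates block duplications from single-repeat-scale
#' changes, which show up as short gaps or mismatches instead.
#'
#' @param query,ref `mature_subunit` objects (or plain protein strings, in
#'   which case the type check is skipped).
#' @param min_block Minimum block length in residues.
#' @param lexicon Motif lexicon for the block census.
#' @param params Alignment parameters.
#' @return List of `insertion_block` objects: `query_span` (1-based span in
#'   query coordinates), `length`, `fragment`, `census`.
#' @export
detect_insertions <- function(query, ref, min_block = 30L,
                              lexicon = default_lexicon(),
                              params = default_align_params()) {
  if (inherits(query, "mature_subunit") && inherits(ref, "mature_subunit")) {
    if (query$subunit_type != ref$subunit_type)
      stop("subunit type mismatch: query is ", query$subunit_type,
           ", reference is ", ref$subunit_type)
    q <- query$residues
    r <- ref$residues
  } else {
    q <- if (inherits(query, "mature_subunit")) query$residues else query
    r <- if (inherits(ref, "mature_subunit")) ref$residues else ref
  }
  aln <- global_align(q, r, params)
  rgap <- chars(aln$aligned_ref) == "-"
  if (!any(rgap)) return(list())
  qpos <- cumsum(chars(aln$aligned_query) != "-")
  runs <- rle(rgap)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_block
  blocks <- lapply(which(keep), function(k) {
    s <- qpos[run_start[k]]
    e <- qpos[run_end[k]]
    sp <- canonicalize_block(q, s, e, lexicon)
    frag <- substr(q, sp[1], sp[2])
    structure(list(query_span = sp, length = nchar(frag), fragment = frag,
                   census = motif_census(segment_repeats(frag, lexicon))),
              class = "insertion_block")
  })
  blocks
}

#' @export
print.insertion_block <- function(x, ...) {
  cat("<insertion_block> query ", x$query_span[1], "-", x$query_span[2],
      " (", x$length, " aa): ", x$census$n_tri, " tri, ", x$census$n_hexa,
      " hexa, ", x$census$n_nona, " nona\n", sep = "")
  invisible(x)
}

#' Verify the tandem-duplication origin of an insertion block
#'
#' Compares the inserted fragment to the equal-length windows immediately
#' upstream and downstream in the query (within the repetitive domain when a
#' partition is supplied), by global alignment. Reports the best-matching
#' flank, percent identity over alignment columns, and the variant positions
#' (1-based within the block). A block touching the domain edge is compared
#' to the remaining flank only, with a note.
#'
#' @param query `mature_subunit` (or protein string) the block was found in.
#' @param block An `insertion_block` from [detect_insertions()].
#' @param partition Optional [partition_domains()] result restricting the
#'   flanking windows to the repetitive domain.
#' @param params Alignment parameters.
#' @return A `duplication_evidence` list: `flank` (`"upstream"` or
#'   `"downstream"`), `identity_pct`, `variant_positions`, `note`,
#'   plus per-flank identities.
#' @export
verify_tandem_duplication <- function(query, block, partition = NULL,
                                      params = default_align_params()) {
  q <- if (inherits(query, "mature_subunit")) query$residues else query
  lo <- 1L
  hi <- nchar(q)
  if (!is.null(partition) && span_len(partition$repetitive) > 0L) {
    lo <- partition$repetitive[1]
    hi <- partition$repetitive[2]
  }
  s <- block$query_span[1]
  e <- block$query_span[2]
  L <- block$length
  flank_cmp <- function(win) {
    aln <- global_align(block$fragment, win, params)
    a <- chars(aln$aligned_query)
    b <- chars(aln$aligned_ref)
    same <- a == b
    bpos <- cumsum(a != "-")
    list(identity = 100 * sum(same) / length(same),
         variants = unique(bpos[!same & bpos >= 1L]))
  }
  up <- if (s - L >= lo) flank_cmp(substr(q, s - L, s - 1L)) else NULL
  dn <- if (e + L <= hi) flank_cmp(substr(q, e + 1L, e + L)) else NULL
  if (is.null(up) && is.null(dn))
    stop("block has no complete flanking window inside the domain")
  note <- if (is.null(up)) "block at upstream domain edge; downstream flank only"
          else if (is.null(dn)) "block at downstream domain edge; upstream flank only"
          else ""
  # Tie prefers downstream (the copy following the original in a tandem
  # duplication).
  pick_dn <- is.null(up) || (!is.null(dn) && dn$identity >= up$identity)
  best <- if (pick_dn) dn else up
  structure(list(
    flank = if (pick_dn) "downstream" else "upstream",
    identity_pct = best$identity,
    variant_positions = sort(best$variants),
    upstream_identity = if (is.null(up)) NA_real_ else up$identity,
    downstream_identity = if (is.null(dn)) NA_real_ else dn$identity,
    note = note
  ), class = "duplication_evidence")
}

#' @export
print.duplication_evidence <- function(x, ...) {
  cat("<duplication_evidence> best flank ", x$flank, ", identity ",
      sprintf("%.1f%%", x$identity_pct), ", ",
      length(x$variant_positions), " variant position(s)\n", sep = "")
  invisible(x)
}
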