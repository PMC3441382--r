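# Annotation of Glu-1 5'-flanking promoters against the six conserved
# cis-regulatory element consensus sequences.

#' Default promoter element set
#'
#' The six conserved cis-regulatory elements of Glu-1 promoters, in their
#' canonical 5'->3' order: E motif, N motif, partial HMW enhancer, complete
#' HMW enhancer, TATA box and transcription start motif. Mismatch caps
#' default to 2 for the 8-9 bp elements, 3 for the 38 bp enhancer and 1 for
#' the 6 bp start motif; known alleles carry up to 2 substitutions in short
#' elements and up to 3 in the enhancer, so stricter caps would misclassify
#' printed alleles as deleted. The enhancer additionally tolerates a single
#' 1 bp deletion (`allow_gap`), as seen in the 1Bx7 promoter.
#'
#' @return A `promoter_elements` data frame with columns `name`,
#'   `consensus`, `max_mismatch`, `allow_gap`.
#' @export
default_elements <- function() {
  el <- data.frame(
    name = c("E_motif", "N_motif", "partial_enhancer", "enhancer",
             "TATA_box", "start_motif"),
    consensus = c(
      "TGTAACCC",
      "TGAGTCAT",
      "TTTGCAAA",
      "GTTTTGCAAAGCTCCAATTGCTCCTTGCTTATCCAGCT",
      "CTATAAAAG",
      "TTATCA"
    ),
    max_mismatch = c(2L, 2L, 2L, 3L, 2L, 1L),
    allow_gap = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  stopifnot(nchar(el$consensus) == c(8L, 8L, 8L, 38L, 9L, 6L))
  structure(el, class = c("promoter_elements", "data.frame"))
}

#' Read a promoter element set from a config file
#'
#' Plain TSV with columns `name`, `consensus`, `max_mismatch` and optional
#' `allow_gap`; `#` lines are comments. Row order defines the canonical
#' 5'->3' element order.
#'
#' @param path Path to the element file.
#' @return A `promoter_elements` data frame.
#' @export
read_elements <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (is.null(df$allow_gap)) df$allow_gap <- FALSE
  df$consensus <- toupper(df$consensus)
  df$max_mismatch <- as.integer(df$max_mismatch)
  structure(df[, c("name", "consensus", "max_mismatch", "allow_gap")],
            class = c("promoter_elements", "data.frame"))
}

#' Substitutions of an observed element relative to its consensus
#'
#' Positional (Hamming) comparison of two equal-length DNA strings.
#'
#' @param observed,consensus Equal-length DNA strings.
#' @return Data frame with columns `position` (1-based within the element),
#'   `consensus_base`, `observed_base`; zero rows when identical.
#' @export
compare_to_consensus <- function(observed, consensus) {
  observed <- toupper(observed)
  consensus <- toupper(consensus)
  if (nchar(observed) != nchar(consensus))
    stop("observed (", nchar(observed), " bp) and consensus (",
         nchar(consensus), " bp) lengths differ")
  a <- chars(observed)
  b <- chars(consensus)
  idx <- which(a != b)
  data.frame(position = idx, consensus_base = b[idx], observed_base = a[idx],
             stringsAsFactors = FALSE)
}

# Best window for one element inside promoter[lo..hi].
# Returns list(offset, observed, mismatches, gap_position) or NULL when no
# window satisfies the mismatch cap. Candidates are ranked by mismatches,
# then ungapped before gapped, then leftmost. A gapped candidate is a
# window of length L-1 scored against the consensus with one consensus base
# (never the first or last) deleted.
best_element_hit <- function(prom_ch, lo, hi, consensus, max_mismatch,
                             allow_gap) {
  L <- nchar(consensus)
  cch <- chars(consensus)
  best <- NULL
  consider <- function(cand) {
    if (is.null(best) ||
        cand$mismatches < best$mismatches ||
        (cand$mismatches == best$mismatches &&
         is.na(best$gap_position) < is.na(cand$gap_position))) {
      best <<- cand
    }
  }
  if (hi - lo + 1L >= L) {
    for (off in lo:(hi - L + 1L)) {
      mm <- sum(prom_ch[off:(off + L - 1L)] != cch)
      if (mm <= max_mismatch) consider(list(
        offset = off, observed = collapse(prom_ch[off:(off + L - 1L)]),
        mismatches = mm, gap_position = NA_integer_))
    }
  }
  if (allow_gap && hi - lo + 1L >= L - 1L) {
    for (off in lo:(hi - L + 2L)) {
      win <- prom_ch[off:(off + L - 2L)]
      for (g in 2:(L - 1L)) {
        mm <- sum(win != cch[-g])
        if (mm <= max_mismatch) consider(list(
          offset = off, observed = collapse(win), mismatches = mm,
          gap_position = g))
      }
    }
  }
  best
}

#' Annotate a promoter against the regulatory element set
#'
#' Locates each element's best-scoring window (fewest substitutions, ties
#' broken ungapped-first then leftmost) subject to two constraints: found
#' elements must not overlap, and they must occur in the canonical 5'->3'
#' element order. Elements are anchored longest-consensus-first (ties by
#' canonical order) so that short elements cannot capture fragments of
#' longer ones -- the partial enhancer core is a verbatim substring of the
#' complete enhancer. An element with no qualifying window is reported
#' `deleted`.
#'
#' @param promoter DNA string (gene orientation; the given strand only is
#'   searched).
#' @param elements A `promoter_elements` set, see [default_elements()].
#' @return A `promoter_annotation`: `elements` data frame (canonical order;
#'   columns `name`, `status`, `offset`, `observed`, `n_substitutions`,
#'   `gap_position`) and `substitutions`, a named list of
#'   [compare_to_consensus()] data frames for found, ungapped elements.
#' @export
scan_elements <- function(promoter, elements = default_elements()) {
  promoter <- toupper(promoter)
  if (nchar(promoter) < max(nchar(elements$consensus)))
    stop("promoter (", nchar(promoter),
         " bp) shorter than the longest element")
  prom_ch <- chars(promoter)
  ne <- nrow(elements)
  hits <- vector("list", ne)
  # Anchor longest elements first; canonical order breaks ties.
  for (k in order(-nchar(elements$consensus), seq_len(ne))) {
    # Search interval consistent with canonical order and non-overlap
    # relative to already-anchored elements.
    lo <- 1L
    hi <- nchar(promoter)
    for (j in seq_len(ne)) {
      if (is.null(hits[[j]])) next
      end_j <- hits[[j]]$offset + nchar(hits[[j]]$observed) - 1L
      if (j < k) lo <- max(lo, end_j + 1L)
      if (j > k) hi <- min(hi, hits[[j]]$offset - 1L)
    }
    if (lo > hi) next
    hits[k] <- list(best_element_hit(prom_ch, lo, hi, elements$consensus[k],
                                     elements$max_mismatch[k],
                                     elements$allow_gap[k]))
  }
  rows <- lapply(seq_len(ne), function(k) {
    h <- hits[[k]]
    if (is.null(h)) {
      data.frame(name = elements$name[k], status = "deleted",
                 offset = NA_integer_, observed = NA_character_,
                 n_substitutions = NA_integer_, gap_position = NA_integer_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(name = elements$name[k], status = "found",
                 offset = h$offset, observed = h$observed,
                 n_substitutions = h$mismatches, gap_position = h$gap_position,
                 stringsAsFactors = FALSE)
    }
  })
  df <- do.call(rbind, rows)
  subs <- list()
  for (k in seq_len(ne)) {
    h <- hits[[k]]
    if (!is.null(h) && is.na(h$gap_position))
      subs[[elements$name[k]]] <-
        compare_to_consensus(h$observed, elements$consensus[k])
  }
  structure(list(elements = df, substitutions = subs,
                 promoter_length = nchar(promoter)),
            class = "promoter_annotation")
}

#' @export
print.promoter_annotation <- function(x, ...) {
  cat("<promoter_annotation> ", x$promoter_length, " bp promoter\n",
      sep = "")
  df <- x$elements
  for (i in seq_len(nrow(df))) {
    if (df$status[i] == "deleted") {
      cat("  ", format(df$name[i], width = 16), " deleted\n", sep = "")
    } else {
      cat("  ", format(df$name[i], width = 16), " @", df$offset[i], " ",
          df$observed[i], " (", df$n_substitutions[i], " subs",
          if (!is.na(df$gap_position[i])) ", 1 bp deletion" else "",
          ")\n", sep = "")
    }
  }
  invisible(x)
}
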