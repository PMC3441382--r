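# Repeat-motif grammar: lexicon, dynamic-programming segmentation of the
# repetitive domain, and motif censuses.

#' Motif lexicon
#'
#' The repetitive domain of HMW-GSs is built from tripeptide, hexapeptide
#' and nonapeptide repeat motifs. A lexicon lists the consensus string and
#' per-motif mismatch cap for each motif class.
#'
#' @param class Character vector in `{"tri","hexa","nona"}`.
#' @param consensus Consensus protein strings of length 3, 6 or 9 matching
#'   `class`.
#' @param max_mismatch Integer mismatch caps, each smaller than its motif
#'   length.
#' @return A `motif_lexicon` data frame.
#' @export
motif_lexicon <- function(class, consensus, max_mismatch) {
  class <- match.arg(class, c("tri", "hexa", "nona"), several.ok = TRUE)
  consensus <- toupper(consensus)
  expected <- c(tri = 3L, hexa = 6L, nona = 9L)
  if (any(nchar(consensus) != expected[class]))
    stop("consensus length does not match motif class")
  max_mismatch <- as.integer(max_mismatch)
  if (any(max_mismatch < 0L) || any(max_mismatch >= nchar(consensus)))
    stop("max_mismatch must be in [0, motif length)")
  structure(
    data.frame(class = class, consensus = consensus,
               max_mismatch = max_mismatch, stringsAsFactors = FALSE),
    class = c("motif_lexicon", "data.frame")
  )
}

#' Default HMW-GS motif lexicon
#'
#' Canonical glutenin repeat motifs: tripeptide `GQQ` (1 mismatch allowed),
#' hexapeptide `PGQGQQ` (2), and nonapeptide `GYYPTSPQQ` with its common
#' variant `GYYPTSLQQ` (2 each). User-overridable; see [read_lexicon()].
#'
#' @return A [motif_lexicon()].
#' @export
default_lexicon <- function() {
  motif_lexicon(
    class = c("tri", "hexa", "nona", "nona"),
    consensus = c("GQQ", "PGQGQQ", "GYYPTSPQQ", "GYYPTSLQQ"),
    max_mismatch = c(1L, 2L, 2L, 2L)
  )
}

#' Read a motif lexicon from a config file
#'
#' Plain TSV with columns `class`, `consensus`, `max_mismatch`; `#` lines
#' are comments.
#'
#' @param path Path to the lexicon file.
#' @return A [motif_lexicon()].
#' @export
read_lexicon <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  motif_lexicon(df$class, df$consensus, df$max_mismatch)
}

#' Segment a repetitive domain into motif tokens
#'
#' Deterministic dynamic-programming parse of the domain into lexicon motif
#' tokens and unassigned runs. The optimum minimizes, in order: (1) the
#' number of unassigned residues, (2) the total mismatches across tokens;
#' among equally optimal parses, longer motifs are preferred earlier in the
#' sequence. Mismatch is Hamming distance (no indels within a token).
#'
#' @param domain Protein string (the repetitive domain). May be empty.
#' @param lexicon A [motif_lexicon()]; an empty lexicon leaves every residue
#'   unassigned.
#' @return An object of class `repeat_segmentation`: `tokens` (data frame
#'   with 1-based `start`, `class`, `observed`, `mismatches`), `unassigned`
#'   (data frame of `start`, `end` spans), `domain`, `n_unassigned`,
#'   `total_mismatches`.
#' @export
segment_repeats <- function(domain, lexicon = default_lexicon()) {
  domain <- toupper(domain)
  n <- nchar(domain)
  empty_tokens <- data.frame(start = integer(), class = character(),
                             observed = character(), mismatches = integer(),
                             stringsAsFactors = FALSE)
  if (n == 0L) {
    return(structure(list(tokens = empty_tokens,
                          unassigned = data.frame(start = integer(),
                                                  end = integer()),
                          domain = domain, n_unassigned = 0L,
                          total_mismatches = 0L),
                     class = "repeat_segmentation"))
  }
  ch <- chars(domain)
  nmot <- nrow(lexicon)
  mot_ch <- lapply(lexicon$consensus, chars)
  mot_len <- nchar(lexicon$consensus)
  # Cost encoding: unassigned * BIG + mismatches, BIG > max possible
  # mismatches, so unassigned dominates lexicographically.
  BIG <- n + 1
  # g[i] = optimal cost of segmenting domain[i..n]; g[n+1] = 0.
  g <- numeric(n + 1L)
  g[n + 1L] <- 0
  for (i in n:1) {
    best <- g[i + 1L] + BIG  # leave residue i unassigned
    if (nmot > 0L) for (r in seq_len(nmot)) {
      L <- mot_len[r]
      if (i + L - 1L > n) next
      mm <- sum(ch[i:(i + L - 1L)] != mot_ch[[r]])
      if (mm <= lexicon$max_mismatch[r])
        best <- min(best, g[i + L] + mm)
    }
    g[i] <- best
  }
  # Reconstruct left to right, preferring longer motifs (then lexicon
  # order) over shorter ones and over skipping, at equal optimal cost.
  pref <- if (nmot > 0L) order(-mot_len, seq_len(nmot)) else integer()
  tokens <- list()
  skipped <- logical(n)
  i <- 1L
  while (i <= n) {
    chosen <- FALSE
    for (r in pref) {
      L <- mot_len[r]
      if (i + L - 1L > n) next
      mm <- sum(ch[i:(i + L - 1L)] != mot_ch[[r]])
      if (mm <= lexicon$max_mismatch[r] && g[i + L] + mm == g[i]) {
        tokens[[length(tokens) + 1L]] <- list(
          start = i, class = lexicon$class[r],
          observed = collapse(ch[i:(i + L - 1L)]), mismatches = mm)
        i <- i + L
        chosen <- TRUE
        break
      }
    }
    if (!chosen) {
      skipped[i] <- TRUE
      i <- i + 1L
    }
  }
  tok_df <- if (length(tokens)) {
    data.frame(start = vapply(tokens, `[[`, 1L, "start"),
               class = vapply(tokens, `[[`, "", "class"),
               observed = vapply(tokens, `[[`, "", "observed"),
               mismatches = vapply(tokens, `[[`, 1L, "mismatches"),
               stringsAsFactors = FALSE)
  } else empty_tokens
  runs <- rle(skipped)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  un_df <- data.frame(start = starts[runs$values], end = ends[runs$values])
  out <- structure(
    list(tokens = tok_df, unassigned = un_df, domain = domain,
         n_unassigned = sum(skipped),
         total_mismatches = sum(tok_df$mismatches)),
    class = "repeat_segmentation"
  )
  # Length-accounting identity, asserted on every output.
  cen <- motif_census(out)
  stopifnot(3L * cen$n_tri + 6L * cen$n_hexa + 9L * cen$n_nona +
              cen$n_unassigned_residues == n)
  out
}

#' @export
print.repeat_segmentation <- function(x, ...) {
  cen <- motif_census(x)
  cat("<repeat_segmentation> ", nchar(x$domain), " aa: ", cen$n_tri,
      " tri, ", cen$n_hexa, " hexa, ", cen$n_nona, " nona, ",
      x$n_unassigned, " unassigned (", x$total_mismatches,
      " mismatches)\n", sep = "")
  invisible(x)
}

#' Census motif classes of a segmentation
#'
#' @param seg A [segment_repeats()] result.
#' @return A `motif_census` list: `n_tri`, `n_hexa`, `n_nona`,
#'   `n_unassigned_residues`, `total_residues`. The identity
#'   `3*n_tri + 6*n_hexa + 9*n_nona + n_unassigned_residues ==
#'   total_residues` always holds.
#' @export
motif_census <- function(seg) {
  stopifnot(inherits(seg, "repeat_segmentation"))
  structure(list(
    n_tri = sum(seg$tokens$class == "tri"),
    n_hexa = sum(seg$tokens$class == "hexa"),
    n_nona = sum(seg$tokens$class == "nona"),
    n_unassigned_residues = as.integer(seg$n_unassigned),
    total_residues = nchar(seg$domain)
  ), class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  cat("<motif_census> tri:", x$n_tri, " hexa:", x$n_hexa, " nona:",
      x$n_nona, " unassigned:", x$n_unassigned_residues, " total:",
      x$total_residues, "\n", sep = "")
  invisible(x)
}

#' Closed-form residue accounting for motif counts
#'
#' Total residues contributed by a motif composition:
#' `3*n_tri + 6*n_hexa + 9*n_nona`.
#'
#' @param n_tri,n_hexa,n_nona Non-negative motif counts.
#' @return Integer residue total.
#' @export
census_length <- function(n_tri, n_hexa, n_nona) {
  counts <- c(n_tri, n_hexa, n_nona)
  if (any(counts < 0)) stop("motif counts must be non-negative")
  as.integer(3L * n_tri + 6L * n_hexa + 9L * n_nona)
}
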