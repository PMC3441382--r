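# Mature-subunit anatomy: signal peptide removal, x/y typing, domain
# partition and cysteine census.

# Mature HMW-GS subunits begin with this conserved pentapeptide; everything
# upstream of its leftmost occurrence (within the first 40 residues) is the
# secretory signal peptide.
MATURE_START_SIGNATURE <- "EGEAS"

#' Strip the signal peptide from a deduced HMW-GS protein
#'
#' The mature subunit starts at the conserved `EGEAS` anchor; the prefix
#' before its leftmost occurrence (searched within the first 40 residues) is
#' the signal peptide. When the anchor is absent nothing is stripped and the
#' subunit is returned with `status = "no_signature"` and type `"unknown"`.
#'
#' @param protein Protein string (or an [translate_orf()] result).
#' @param id Identifier carried through to the result.
#' @return An object of class `mature_subunit`: fields `id`, `residues`
#'   (mature sequence), `signal_peptide`, `subunit_type` (`"x"`, `"y"` or
#'   `"unknown"`) and `status`.
#' @export
strip_signal_peptide <- function(protein, id = "subunit") {
  if (inherits(protein, "orf_translation")) protein <- protein$residues
  stopifnot(is.character(protein), length(protein) == 1L)
  hit <- regexpr(MATURE_START_SIGNATURE, protein, fixed = TRUE)
  if (hit == -1L || hit > 40L) {
    warning("mature-start signature '", MATURE_START_SIGNATURE,
            "' not found in first 40 residues of '", id,
            "'; signal peptide not stripped")
    return(structure(list(id = id, residues = protein, signal_peptide = "",
                          subunit_type = "unknown", status = "no_signature"),
                     class = "mature_subunit"))
  }
  mature <- substr(protein, hit, nchar(protein))
  out <- structure(
    list(id = id, residues = mature,
         signal_peptide = substr(protein, 1L, hit - 1L),
         subunit_type = "unknown", status = "ok"),
    class = "mature_subunit"
  )
  out$subunit_type <- classify_subunit_type(out)
  out
}

#' @export
print.mature_subunit <- function(x, ...) {
  cat("<mature_subunit> ", x$id, ": ", nchar(x$residues), " aa mature, ",
      nchar(x$signal_peptide), " aa signal, type ", x$subunit_type,
      " (", x$status, ")\n", sep = "")
  invisible(x)
}

#' Classify a mature subunit as x-type or y-type
#'
#' Residue 6 of the mature N-terminus distinguishes the two HMW-GS
#' subfamilies: `G`/`E` marks x-type and `R`/`K` marks y-type. When residue
#' 6 is uninformative (e.g. `X`), the N-terminal domain length from the
#' domain partition is used instead (about 81-89 residues for x-type, about
#' 104 for y-type); failing both, `"unknown"` is returned.
#'
#' @param mature A `mature_subunit` or a mature protein string.
#' @param lexicon Motif lexicon used for the fallback domain partition.
#' @return `"x"`, `"y"` or `"unknown"`.
#' @export
classify_subunit_type <- function(mature, lexicon = default_lexicon()) {
  res <- if (inherits(mature, "mature_subunit")) mature$residues else mature
  if (nchar(res) < 12L) return("unknown")
  r6 <- substr(res, 6L, 6L)
  if (r6 %in% c("G", "E")) return("x")
  if (r6 %in% c("R", "K")) return("y")
  if (nchar(res) < 43L) return("unknown")
  ms <- if (inherits(mature, "mature_subunit")) mature else
    structure(list(id = "q", residues = res, signal_peptide = "",
                   subunit_type = "unknown", status = "ok"),
              class = "mature_subunit")
  part <- partition_domains(ms, lexicon)
  nt <- span_len(part$n_terminal)
  if (nt >= 75L && nt <= 95L) return("x")
  if (nt >= 96L && nt <= 115L) return("y")
  "unknown"
}

# TRUE when >= k consecutive lexicon motifs (each within its mismatch cap)
# tile the sequence starting at position i.
matches_consecutive <- function(ch, i, lexicon, k) {
  if (k == 0L) return(TRUE)
  n <- length(ch)
  ord <- order(-nchar(lexicon$consensus))
  for (r in ord) {
    L <- nchar(lexicon$consensus[r])
    if (i + L - 1L > n) next
    if (hamming(ch[i:(i + L - 1L)], chars(lexicon$consensus[r])) <=
        lexicon$max_mismatch[r]) {
      if (matches_consecutive(ch, i + L, lexicon, k - 1L)) return(TRUE)
    }
  }
  FALSE
}

#' Partition a mature subunit into N-terminal, repetitive and C-terminal
#' domains
#'
#' The C-terminal domain is the final 42 residues (constant across known
#' alleles). The repetitive domain starts at the first position from which
#' at least three consecutive lexicon motifs match (robust to isolated
#' spurious motif hits) and runs to the C-terminal boundary; the N-terminal
#' domain is the prefix. If no repeat onset is found the whole body before
#' the C-terminal domain is reported as N-terminal with a warning status.
#'
#' @param mature A `mature_subunit` or mature protein string.
#' @param lexicon A [motif_lexicon()].
#' @return An object of class `domain_partition`: 1-based inclusive spans
#'   `n_terminal`, `repetitive` (NULL when empty), `c_terminal`, plus
#'   `status`.
#' @export
partition_domains <- function(mature, lexicon = default_lexicon()) {
  res <- if (inherits(mature, "mature_subunit")) mature$residues else mature
  n <- nchar(res)
  if (n < 43L) stop("mature sequence too short to partition (", n, " aa)")
  cterm <- c(n - 41L, n)
  body_end <- n - 42L
  ch <- chars(res)
  onset <- NA_integer_
  for (i in seq_len(body_end)) {
    if (matches_consecutive(ch, i, lexicon, 3L)) { onset <- i; break }
  }
  if (is.na(onset) || onset > body_end) {
    part <- list(n_terminal = c(1L, body_end), repetitive = NULL,
                 c_terminal = cterm, status = "no_repeats")
    warning("no repeat onset found; repetitive domain empty")
  } else {
    part <- list(
      n_terminal = if (onset > 1L) c(1L, onset - 1L) else NULL,
      repetitive = c(onset, body_end),
      c_terminal = cterm, status = "ok"
    )
  }
  structure(part, class = "domain_partition")
}

#' @export
print.domain_partition <- function(x, ...) {
  fmt <- function(sp) if (span_len(sp) == 0L) "-" else
    paste0(sp[1], "-", sp[2], " (", span_len(sp), " aa)")
  cat("<domain_partition> N-terminal ", fmt(x$n_terminal),
      "; repetitive ", fmt(x$repetitive),
      "; C-terminal ", fmt(x$c_terminal), "\n", sep = "")
  invisible(x)
}

#' Census cysteine residues per domain
#'
#' Counts cysteines in the N-terminal, repetitive and C-terminal domains.
#' Conforming x-type subunits carry (3, 0, 1) and y-type (5, 1, 1); the
#' x-type pattern (3, 1, 1) with an extra repetitive-domain cysteine (as in
#' 1Dx5) is also treated as known. `conforms` flags whether the observed
#' pattern matches a known one for the subunit type.
#'
#' @param mature A `mature_subunit`.
#' @param partition Its [partition_domains()] result.
#' @return A `cysteine_census` list: `n_nterm`, `n_rep`, `n_cterm`,
#'   `n_total`, `conforms`.
#' @export
cysteine_census <- function(mature, partition) {
  res <- if (inherits(mature, "mature_subunit")) mature$residues else mature
  count_c <- function(span) {
    s <- span_str(res, span)
    if (!nzchar(s)) 0L else sum(chars(s) == "C")
  }
  n_nterm <- count_c(partition$n_terminal)
  n_rep <- count_c(partition$repetitive)
  n_cterm <- count_c(partition$c_terminal)
  type <- if (inherits(mature, "mature_subunit")) mature$subunit_type
          else "unknown"
  pat <- c(n_nterm, n_rep, n_cterm)
  conforms <- switch(type,
    x = identical(pat, c(3L, 0L, 1L)) || identical(pat, c(3L, 1L, 1L)),
    y = identical(pat, c(5L, 1L, 1L)),
    NA
  )
  structure(list(n_nterm = n_nterm, n_rep = n_rep, n_cterm = n_cterm,
                 n_total = n_nterm + n_rep + n_cterm, conforms = conforms),
            class = "cysteine_census")
}

#' @export
print.cysteine_census <- function(x, ...) {
  cat("<cysteine_census> N:", x$n_nterm, " R:", x$n_rep, " C:", x$n_cterm,
      " total:", x$n_total,
      if (isTRUE(x$conforms)) " (conforming)" else "", "\n", sep = "")
  invisible(x)
}
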