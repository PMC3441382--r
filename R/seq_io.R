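#' Gene record
#'
#' A light container pairing an HMW-GS open reading frame with its optional
#' 5'-flanking promoter sequence.
#'
#' @param id Record identifier (unique within a set).
#' @param orf_dna DNA string of the complete ORF (A/C/G/T/N, any case;
#'   stored upper-case). Must start with ATG and have length divisible by 3.
#' @param promoter_dna Optional DNA string of the 5' flanking promoter.
#' @param source Free-text provenance.
#' @return An object of class `gene_record`.
#' @export
gene_record <- function(id, orf_dna, promoter_dna = NULL, source = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  orf_dna <- toupper(orf_dna)
  bad <- regmatches(orf_dna, regexpr("[^ACGTN]", orf_dna))
  if (length(bad) && nzchar(bad))
    stop("illegal character '", bad, "' in ORF of record '", id, "'")
  if (!is.null(promoter_dna)) {
    promoter_dna <- toupper(promoter_dna)
    bad <- regmatches(promoter_dna, regexpr("[^ACGTN]", promoter_dna))
    if (length(bad) && nzchar(bad))
      stop("illegal character '", bad, "' in promoter of record '", id, "'")
  }
  structure(
    list(id = id, orf_dna = orf_dna, promoter_dna = promoter_dna,
         source = source),
    class = "gene_record"
  )
}

#' @export
print.gene_record <- function(x, ...) {
  cat("<gene_record>", x$id, "\n")
  cat("  ORF:", nchar(x$orf_dna), "bp")
  if (!is.null(x$promoter_dna))
    cat("; promoter:", nchar(x$promoter_dna), "bp")
  cat("\n")
  invisible(x)
}

# Scan the raw FASTA text for the first character not in `allowed`
# (sequence lines only) and return its line number, or NA.
locate_illegal_line <- function(path, allowed) {
  lines <- readLines(path, warn = FALSE)
  pat <- paste0("[^", allowed, "]")
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">") || !nzchar(ln)) next
    if (grepl(pat, toupper(ln))) return(i)
  }
  NA_integer_
}

#' Read a FASTA file
#'
#' Reads plain FASTA into a named character vector of upper-case sequences.
#' Ids are the first whitespace-delimited token of each header and must be
#' unique. Promoter records follow the `_prom` id-suffix dialect used by
#' [read_gene_records()].
#'
#' @param path Path to a FASTA file.
#' @param type `"dna"`, `"protein"` or `"auto"` (default): controls alphabet
#'   validation. DNA allows `ACGTN`; protein allows the 20 amino-acid
#'   letters plus `X` and `*`.
#' @return Named character vector of sequences, input order preserved.
#' @export
read_fasta <- function(path, type = c("auto", "dna", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("malformed FASTA '", path, "': ",
                                          conditionMessage(e)))
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(ss))
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  names(seqs) <- ids
  if (type == "auto")
    type <- if (all(grepl("^[ACGTN]*$", seqs))) "dna" else "protein"
  allowed <- if (type == "dna") "ACGTN" else "ACDEFGHIKLMNPQRSTVWYX*"
  ok <- grepl(paste0("^[", gsub("\\*", "\\\\*", allowed), "]*$"), seqs)
  if (!all(ok)) {
    line <- locate_illegal_line(path, allowed)
    stop("illegal character for ", type, " alphabet in record '",
         ids[!ok][1], "' (line ", line, " of ", path, ")")
  }
  seqs
}

#' Read linked ORF/promoter gene records
#'
#' Reads a DNA FASTA in which a promoter sequence for record `x` is supplied
#' as a separate record with id `x_prom`, and returns one [gene_record()]
#' per ORF with the promoter attached.
#'
#' @param path Path to a DNA FASTA file.
#' @param source Provenance string stored on every record.
#' @return List of `gene_record` objects, ORF order preserved.
#' @export
read_gene_records <- function(path, source = path) {
  seqs <- read_fasta(path, type = "dna")
  is_prom <- grepl("_prom$", names(seqs))
  proms <- seqs[is_prom]
  orfs <- seqs[!is_prom]
  orphan <- setdiff(sub("_prom$", "", names(proms)), names(orfs))
  if (length(orphan))
    warning("promoter record(s) without matching ORF: ",
            paste(orphan, collapse = ", "))
  lapply(names(orfs), function(id) {
    key <- paste0(id, "_prom")
    prom <- if (key %in% names(proms)) proms[[key]] else NULL
    gene_record(id, orfs[[id]], promoter_dna = prom, source = source)
  })
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Translate an HMW-GS open reading frame
#'
#' Standard genetic code translation with the stop-codon accounting these
#' genes require: translation stops at the first in-frame stop; one or two
#' stop codons at the very end of the ORF (tandem stops such as `TGATAG` are
#' typical of Glu-1 ORFs) are consumed and counted rather than translated.
#' A stop followed by further sense codons marks the ORF as pseudogene-like:
#' the translation up to the stop is returned with a warning status. Any
#' codon containing `N` translates to `X` and is never treated as a stop.
#'
#' @param orf DNA string; must start with `ATG` and have length a multiple
#'   of 3.
#' @return An object of class `orf_translation` with fields `residues`
#'   (protein string without stops), `n_codons` (total codons including
#'   stops), `n_trailing_stops` (0, 1 or 2) and `status` (`"ok"` or
#'   `"premature_stop"`).
#' @export
translate_orf <- function(orf) {
  orf <- toupper(orf)
  if (nchar(orf) < 3L) stop("ORF shorter than one codon")
  if (!startsWith(orf, "ATG")) stop("ORF does not begin with ATG")
  if (nchar(orf) %% 3L != 0L)
    stop("ORF length (", nchar(orf), ") is not a multiple of 3")
  n <- nchar(orf) %/% 3L
  codons <- substring(orf, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  code <- Biostrings::GENETIC_CODE
  aa <- ifelse(grepl("N", codons, fixed = TRUE), "X",
               unname(code[codons]))
  stop_at <- which(aa == "*")
  if (length(stop_at) == 0L) {
    return(structure(list(residues = collapse(aa), n_codons = n,
                          n_trailing_stops = 0L, status = "ok"),
                     class = "orf_translation"))
  }
  first <- stop_at[1L]
  trailing <- aa[first:n]
  if (all(trailing == "*") && length(trailing) <= 2L) {
    status <- "ok"
    n_trail <- length(trailing)
  } else {
    status <- "premature_stop"
    n_trail <- 0L
    warning("internal premature stop at codon ", first,
            "; pseudogene-like ORF, translation truncated")
  }
  structure(list(residues = collapse(aa[seq_len(first - 1L)]),
                 n_codons = n, n_trailing_stops = n_trail, status = status),
            class = "orf_translation")
}

#' @export
print.orf_translation <- function(x, ...) {
  cat("<orf_translation> ", nchar(x$residues), " aa; ", x$n_codons,
      " codons; ", x$n_trailing_stops, " trailing stop(s); status=",
      x$status, "\n", sep = "")
  invisible(x)
}

#' Write an annotation report
#'
#' Writes a data frame of annotations as TSV or JSON. Every report starts
#' with header lines stating that all coordinates are 1-based inclusive,
#' plus any caller-supplied metadata lines; identical inputs produce
#' bit-identical files.
#'
#' @param annotations A data frame (may have zero rows).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param metadata Character vector of extra header/metadata lines.
#' @return `path`, invisibly.
#' @export
write_report <- function(annotations, path, format = c("tsv", "json"),
                         metadata = character()) {
  format <- match.arg(format)
  stopifnot(is.data.frame(annotations))
  header <- c("glutannot report; all coordinates 1-based inclusive", metadata)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", header), con)
    utils::write.table(annotations, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(list(metadata = header, rows = annotations),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
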