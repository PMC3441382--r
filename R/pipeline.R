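# Orchestration: annotate subunits, compare to references, annotate
# promoters, run phylogeny -- with reproducible, header-stamped outputs.

# 32-bit FNV-1a hash of a string, as 8 hex digits; used only to echo a
# config fingerprint into output headers.
fnv1a_hex <- function(s) {
  h <- 0x811c9dc5
  p <- 16777619
  for (b in utf8ToInt(s)) {
    # XOR into the low byte (b < 256), keeping h a double in [0, 2^32).
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply in halves to stay within double precision.
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Pipeline run configuration
#'
#' Bundles every tunable parameter of the pipeline with its documented
#' default; the configuration fingerprint is echoed into every output
#' header so identical configs give identical outputs.
#'
#' @param lexicon Motif lexicon ([default_lexicon()]).
#' @param align_params Alignment scores ([default_align_params()]).
#' @param min_block Minimum insertion block length in residues.
#' @param elements Promoter element set ([default_elements()]).
#' @param n_boot Bootstrap replicates for the NJ tree.
#' @param seed RNG seed for the bootstrap.
#' @param epsilon,weights Median-joining network parameters.
#' @return A `run_config` list with a `hash` fingerprint.
#' @export
run_config <- function(lexicon = default_lexicon(),
                       align_params = default_align_params(),
                       min_block = 30L,
                       elements = default_elements(),
                       n_boot = 1000L, seed = 1L,
                       epsilon = 0, weights = 10) {
  cfg <- list(lexicon = lexicon, align_params = align_params,
              min_block = as.integer(min_block), elements = elements,
              n_boot = as.integer(n_boot), seed = as.integer(seed),
              epsilon = epsilon, weights = weights)
  cfg$hash <- fnv1a_hex(jsonlite::toJSON(
    cfg[c("align_params", "min_block", "n_boot", "seed", "epsilon",
          "weights")],
    auto_unbox = TRUE, digits = NA))
  structure(cfg, class = "run_config")
}

config_header <- function(config) {
  c(paste0("glutannot ", as.character(utils::packageVersion("glutannot"))),
    paste0("config=", config$hash, "; seed=", config$seed))
}

as_gene_records <- function(input) {
  if (is.character(input) && length(input) == 1L && file.exists(input))
    read_gene_records(input)
  else if (is.list(input) && all(vapply(input, inherits, TRUE, "gene_record")))
    input
  else stop("input must be a FASTA path or a list of gene_record objects")
}

# Full single-record annotation; internal workhorse shared by run_annotate
# and run_compare.
annotate_one <- function(record, config) {
  tr <- translate_orf(record$orf_dna)
  mature <- strip_signal_peptide(tr, id = record$id)
  part <- partition_domains(mature, config$lexicon)
  cys <- cysteine_census(mature, part)
  list(record = record, translation = tr, mature = mature,
       partition = part, cysteines = cys)
}

annotation_row <- function(a) {
  data.frame(
    id = a$record$id,
    orf_bp = nchar(a$record$orf_dna),
    n_codons = a$translation$n_codons,
    n_trailing_stops = a$translation$n_trailing_stops,
    type = a$mature$subunit_type,
    signal_len = nchar(a$mature$signal_peptide),
    nterm_len = span_len(a$partition$n_terminal),
    rep_len = span_len(a$partition$repetitive),
    cterm_len = span_len(a$partition$c_terminal),
    mature_len = nchar(a$mature$residues),
    cys_nterm = a$cysteines$n_nterm,
    cys_rep = a$cysteines$n_rep,
    cys_cterm = a$cysteines$n_cterm,
    cys_total = a$cysteines$n_total,
    cys_conforms = a$cysteines$conforms,
    status = if (a$translation$status != "ok") a$translation$status
             else a$mature$status,
    stringsAsFactors = FALSE
  )
}

empty_annotation <- function() annotation_row(list(
  record = list(id = "x", orf_dna = ""),
  translation = list(n_codons = 0L, n_trailing_stops = 0L, status = "ok"),
  mature = list(subunit_type = "x", signal_peptide = "", residues = "",
                status = "ok"),
  partition = list(n_terminal = NULL, repetitive = NULL, c_terminal = NULL),
  cysteines = list(n_nterm = 0L, n_rep = 0L, n_cterm = 0L, n_total = 0L,
                   conforms = TRUE)))[0, ]

#' Annotate HMW-GS gene records
#'
#' Translates each ORF, strips the signal peptide, types the subunit,
#' partitions the domains and censuses cysteines; one report row per
#' record. Per-record problems are downgraded to warnings and the run
#' continues (the row carries a status).
#'
#' @param input FASTA path (promoters via the `_prom` id dialect) or list
#'   of [gene_record()]s.
#' @param config A [run_config()].
#' @param out Optional output path for the report.
#' @param format Report format when `out` is given.
#' @return Data frame of per-subunit annotations (domain lengths sum to the
#'   mature length; cysteine counts per domain and total).
#' @export
run_annotate <- function(input, config = run_config(), out = NULL,
                         format = c("tsv", "json")) {
  records <- tryCatch(as_gene_records(input), error = function(e) {
    if (grepl("empty FASTA", conditionMessage(e))) {
      warning("empty input: ", conditionMessage(e))
      list()
    } else stop(e)
  })
  rows <- lapply(records, function(rec) {
    tryCatch(
      withCallingHandlers(
        annotation_row(annotate_one(rec, config)),
        warning = function(w) {
          warning("record '", rec$id, "': ", conditionMessage(w),
                  call. = FALSE)
          invokeRestart("muffleWarning")
        }),
      error = function(e) {
        warning("record '", rec$id, "' failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
  })
  df <- do.call(rbind, c(list(empty_annotation()), rows))
  rownames(df) <- NULL
  if (!is.null(out))
    write_report(df, out, format = match.arg(format),
                 metadata = config_header(config))
  df
}

#' Compare query subunits to references and report inserted blocks
#'
#' Detects large insertion blocks in each query relative to the same-type
#' reference subunit and reports, per block, the motif composition (counts
#' of tri/hexa/nonapeptides, total residues) and tandem-duplication
#' evidence. Queries without a same-type reference are skipped with a
#' warning.
#'
#' @param query_input,ref_input FASTA paths or [gene_record()] lists; the
#'   reference set must hold at most one reference per subunit type.
#' @param config A [run_config()].
#' @param out Optional report path.
#' @param format Report format when `out` is given.
#' @return Data frame, one row per detected block.
#' @export
run_compare <- function(query_input, ref_input, config = run_config(),
                        out = NULL, format = c("tsv", "json")) {
  queries <- as_gene_records(query_input)
  refs <- as_gene_records(ref_input)
  ref_ann <- lapply(refs, annotate_one, config = config)
  ref_types <- vapply(ref_ann, function(a) a$mature$subunit_type, "")
  if (anyDuplicated(ref_types[ref_types != "unknown"]))
    stop("more than one reference for a subunit type")
  empty <- data.frame(
    id = character(), ref_id = character(), start = integer(),
    end = integer(), length = integer(), n_tri = integer(),
    n_hexa = integer(), n_nona = integer(), total_residues = integer(),
    flank = character(), identity_pct = numeric(), n_variants = integer(),
    stringsAsFactors = FALSE)
  rows <- list(empty)
  for (rec in queries) {
    a <- suppressWarnings(annotate_one(rec, config))
    ri <- which(ref_types == a$mature$subunit_type)
    if (!length(ri)) {
      warning("no ", a$mature$subunit_type, "-type reference for '",
              rec$id, "'; skipped")
      next
    }
    blocks <- detect_insertions(a$mature, ref_ann[[ri]]$mature,
                                min_block = config$min_block,
                                lexicon = config$lexicon,
                                params = config$align_params)
    for (b in blocks) {
      ev <- verify_tandem_duplication(a$mature, b, a$partition,
                                      config$align_params)
      rows[[length(rows) + 1L]] <- data.frame(
        id = rec$id, ref_id = ref_ann[[ri]]$record$id,
        start = b$query_span[1], end = b$query_span[2], length = b$length,
        n_tri = b$census$n_tri, n_hexa = b$census$n_hexa,
        n_nona = b$census$n_nona,
        total_residues = b$census$total_residues,
        flank = ev$flank, identity_pct = ev$identity_pct,
        n_variants = length(ev$variant_positions),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (!is.null(out))
    write_report(df, out, format = match.arg(format),
                 metadata = config_header(config))
  df
}

#' Annotate promoters against the regulatory element set
#'
#' One row per promoter, one column group (`status`, `offset`, `observed`,
#' `n_subs`) per element.
#'
#' @param input Named character vector of promoter DNA strings, or a FASTA
#'   path.
#' @param config A [run_config()].
#' @param out Optional report path.
#' @param format Report format when `out` is given.
#' @return Wide data frame of per-promoter element annotations.
#' @export
run_promoter <- function(input, config = run_config(), out = NULL,
                         format = c("tsv", "json")) {
  proms <- if (is.character(input) && length(input) == 1L &&
               file.exists(input)) read_fasta(input, type = "dna") else input
  rows <- lapply(names(proms), function(id) {
    ann <- scan_elements(proms[[id]], config$elements)$elements
    row <- data.frame(id = id, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(ann))) {
      nm <- ann$name[i]
      row[[paste0(nm, "_status")]] <- ann$status[i]
      row[[paste0(nm, "_offset")]] <- ann$offset[i]
      row[[paste0(nm, "_observed")]] <- ann$observed[i]
      row[[paste0(nm, "_n_subs")]] <- ann$n_substitutions[i]
    }
    row
  })
  df <- do.call(rbind, rows)
  if (!is.null(out))
    write_report(df, out, format = match.arg(format),
                 metadata = config_header(config))
  df
}

#' Run the phylogeny stage: NJ tree with bootstrap plus MJ network
#'
#' @param aligned Named character vector of equal-length aligned DNA
#'   strings, or a FASTA path. With fewer than 3 sequences the NJ tree is
#'   skipped with a warning; the network is still built.
#' @param config A [run_config()].
#' @param out_tree Optional Newick output path (header comment lines first).
#' @param out_network Optional network edge-list output path.
#' @return List with `tree` (phylo with bootstrap node labels, or NULL) and
#'   `network` (a [median_joining_network()] result).
#' @export
run_phylo <- function(aligned, config = run_config(), out_tree = NULL,
                      out_network = NULL) {
  if (is.character(aligned) && length(aligned) == 1L && file.exists(aligned))
    aligned <- read_fasta(aligned, type = "dna")
  tree <- NULL
  if (length(aligned) >= 3L) {
    tree <- bootstrap_support(aligned, n_reps = config$n_boot,
                              seed = config$seed)
  } else {
    warning("fewer than 3 sequences; NJ tree skipped")
  }
  network <- median_joining_network(aligned, epsilon = config$epsilon,
                                    weights = config$weights)
  if (!is.null(out_tree) && !is.null(tree)) {
    writeLines(c(paste0("# ", config_header(config)),
                 ape::write.tree(tree)), out_tree)
  }
  if (!is.null(out_network)) {
    write_report(network$edges, out_network, format = "tsv",
                 metadata = c(config_header(config),
                              sprintf("epsilon=%g; weights=%s",
                                      config$epsilon,
                                      paste(config$weights, collapse = ","))))
    write_report(network$nodes, paste0(out_network, ".nodes.tsv"),
                 format = "tsv", metadata = config_header(config))
  }
  list(tree = tree, network = network)
}
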