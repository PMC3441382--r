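# Seeded generator of HMW-GS-like genes, promoters and sequence families
# with a recorded ground truth, so every pipeline stage can be tested
# without downloads.

# Fixed architecture constants. The 21-residue signal peptide and the
# 42-residue C-terminal are invariant across the generator's output; the
# signal peptide starts MAKR (as real Glu-1 ORFs do) and the C-terminal
# carries exactly one cysteine. Neither contains the EGEAS mature-start
# anchor, G (so no chance repeat-motif onset in flanking filler), nor any
# repeat motif run.
SYN_SIGNAL <- "MAKRLVLFAAVVVALVALTVA"
SYN_CTERM <- "SHVSVEHQAASLKVAKAQQLAAQLPAMCRLEGGDALSASQAQ"

# N-terminal domain templates: conserved start (residue 6 G for x, R for y),
# filler built from a motif-free heptad, cysteines planted to the canonical
# per-type counts (x-type N-terminal: 3, y-type: 5, including the one in
# the conserved start).
syn_nterminal <- function(subunit_type) {
  if (subunit_type == "x") {
    start <- "EGEASGQLQCER"
    len <- 86L
    c_at <- c(30L, 60L)
  } else {
    start <- "EGEASRQLQCER"
    len <- 104L
    c_at <- c(30L, 50L, 70L, 90L)
  }
  filler <- substr(strrep("ELQERAK", ceiling(len / 7)), 1L,
                   len - nchar(start))
  nt <- chars(paste0(start, filler))
  nt[c_at] <- "C"
  collapse(nt)
}

# Reverse the genetic code: codons per amino acid (stops excluded).
codons_by_aa <- function() {
  code <- Biostrings::GENETIC_CODE
  split(names(code), unname(code))
}

# Reverse-translate a protein, sampling uniformly among synonymous codons
# from the current RNG stream.
reverse_translate <- function(protein) {
  tab <- codons_by_aa()
  aa <- chars(protein)
  collapse(vapply(aa, function(a) {
    cs <- tab[[a]]
    if (is.null(cs)) stop("cannot reverse-translate residue '", a, "'")
    cs[sample.int(length(cs), 1L)]
  }, "", USE.NAMES = FALSE))
}

# Build a shuffled vector of motif consensus strings with the given class
# composition; nonapeptide tokens rotate through `nona_variants`.
build_tokens <- function(n_tri, n_hexa, n_nona,
                         nona_variants = c("GYYPTSPQQ", "GYYPTSLQQ")) {
  nonas <- rep(nona_variants, length.out = n_nona)
  toks <- c(rep("GQQ", n_tri), rep("PGQGQQ", n_hexa), nonas)
  if (length(toks) > 1L) toks <- toks[sample.int(length(toks))]
  toks
}

# Ensure chunk `i` of a token-chunk list ends with the GYYPTSLQQ nona
# variant (swapping one in from elsewhere when needed). Duplicated blocks
# planted after such a chunk have an unambiguous upstream boundary: every
# motif ends in QQ, but only this variant ends in LQQ, so a block whose own
# tokens end in GQQ/PQQ cannot slide left across the boundary. Best effort:
# a composition without that variant is left unchanged.
anchor_chunk_end <- function(chunks, i) {
  lqq <- "GYYPTSLQQ"
  if (length(chunks[[i]]) == 0L) return(chunks)
  if (chunks[[i]][length(chunks[[i]])] == lqq) return(chunks)
  k <- which(chunks[[i]] == lqq)
  if (length(k)) {
    last <- length(chunks[[i]])
    chunks[[i]][c(k[1L], last)] <- chunks[[i]][c(last, k[1L])]
    return(chunks)
  }
  for (j in seq_along(chunks)) {
    if (j == i) next
    k <- which(chunks[[j]] == lqq)
    # Never steal another chunk's final token: it may anchor its own block.
    k <- k[k != length(chunks[[j]])]
    if (length(k)) {
      last <- length(chunks[[i]])
      tmp <- chunks[[i]][last]
      chunks[[i]][last] <- chunks[[j]][k[1L]]
      chunks[[j]][k[1L]] <- tmp
      return(chunks)
    }
  }
  chunks
}

#' Generate a synthetic HMW-GS gene with known ground truth
#'
#' Emits a DNA ORF whose translation has the canonical HMW-GS architecture:
#' a 21-residue signal peptide, a conserved N-terminal domain starting
#' `EGEAS(G|R)` with the per-type cysteine complement (x: 3, y: 5), a
#' repetitive domain concatenated from lexicon motifs, and a 42-residue
#' C-terminal with one cysteine. The y-type repetitive-domain cysteine is
#' planted as a single substitution inside one motif token (outside any
#' duplicated block), so the motif parse is unaffected. The ORF ends with
#' the tandem stop codons `TGATAG`. Codon choice is uniform over synonymous
#' codons; everything is drawn from the seeded RNG, so the same seed gives
#' byte-identical output.
#'
#' `insertion` plants a tandem block duplication: a contiguous run of
#' motifs with the stated composition is placed mid-domain and duplicated
#' in place. With `n_subs > 0` that many residues of the second copy are
#' substituted (always including the copy's final residue, which uniquely
#' anchors the variant copy in an alignment); the clean record without the
#' duplication is returned alongside as the reference.
#'
#' @param seed Integer seed.
#' @param subunit_type `"x"` or `"y"`.
#' @param n_tri,n_hexa,n_nona Motif composition of the base repetitive
#'   domain (defaults sized to a typical subunit of the type: x about 690,
#'   y about 480 residues).
#' @param insertion Optional list `(n_tri, n_hexa, n_nona, n_subs = 0)`
#'   describing the duplicated block.
#' @param sub_rate DNA substitution rate in `[0, 0.1]`, applied to the
#'   repetitive-domain codons of the shared pre-duplication sequence: the
#'   gene and its reference carry the same substitutions, emulating the
#'   allele pair's joint divergence from the motif consensus
#'   (stop-creating changes are resampled).
#' @param id Record id.
#' @return List with `record` (the [gene_record()]), `reference` (the
#'   insertion-free, mutation-free counterpart) and `truth` (architecture,
#'   planted spans, mature sequences, seed).
#' @export
generate_subunit <- function(seed, subunit_type = c("x", "y"),
                             n_tri = NULL, n_hexa = NULL, n_nona = NULL,
                             insertion = NULL, sub_rate = 0,
                             id = paste0("syn_", subunit_type[1])) {
  subunit_type <- match.arg(subunit_type)
  stopifnot(sub_rate >= 0, sub_rate <= 0.1)
  defaults <- if (subunit_type == "x") c(21L, 61L, 29L) else c(15L, 40L, 22L)
  n_tri <- as.integer(n_tri %||% defaults[1])
  n_hexa <- as.integer(n_hexa %||% defaults[2])
  n_nona <- as.integer(n_nona %||% defaults[3])
  if (any(c(n_tri, n_hexa, n_nona) < 0)) stop("motif counts must be >= 0")
  main_len <- census_length(n_tri, n_hexa, n_nona)
  # One insertion spec or a list of them.
  specs <- if (is.null(insertion)) list()
    else if (!is.null(names(insertion))) list(insertion)
    else insertion
  specs <- lapply(specs, function(sp) {
    counts <- c(tri = as.integer(sp$n_tri %||% 0L),
                hexa = as.integer(sp$n_hexa %||% 0L),
                nona = as.integer(sp$n_nona %||% 0L))
    len <- census_length(counts[1], counts[2], counts[3])
    if (len == 0L) stop("insertion block must be non-empty")
    if (len > main_len)
      stop("insertion block (", len,
           " aa) longer than the rest of the repetitive domain (",
           main_len, " aa)")
    list(counts = counts, length = len,
         n_subs = as.integer(sp$n_subs %||% 0L))
  })
  nterm <- syn_nterminal(subunit_type)

  with_seed(seed, {
    main_toks <- build_tokens(n_tri, n_hexa, n_nona)
    nb <- length(specs)
    # Split the main tokens into nb+1 consecutive chunks; block i sits
    # between chunks i and i+1, duplicated in the query.
    bounds <- floor(length(main_toks) * seq_len(nb) / (nb + 1L))
    chunks <- unname(split(main_toks,
                           findInterval(seq_along(main_toks),
                                        bounds + 1L) + 1L))
    if (length(chunks) < nb + 1L)
      chunks <- c(chunks, rep(list(character()), nb + 1L - length(chunks)))
    for (i in seq_len(nb)) chunks <- anchor_chunk_end(chunks, i)
    blocks <- lapply(specs, function(sp)
      build_tokens(sp$counts[1], sp$counts[2], sp$counts[3],
                   nona_variants = "GYYPTSPQQ"))
    # y-type repetitive-domain cysteine: one substitution inside a main
    # (non-duplicated, non-chunk-final) token, position 5 of a hexapeptide
    # when available, so the motif parse is unaffected.
    if (subunit_type == "y") {
      planted <- FALSE
      for (target in c("PGQGQQ", "GQQ")) {
        if (planted) break
        for (ci in seq_along(chunks)) {
          hit <- which(chunks[[ci]] == target)
          hit <- hit[hit != length(chunks[[ci]])]
          if (length(hit)) {
            tk <- chars(chunks[[ci]][hit[1L]])
            tk[if (length(tk) >= 6L) 5L else 2L] <- "C"
            chunks[[ci]][hit[1L]] <- collapse(tk)
            planted <- TRUE
            break
          }
        }
      }
    }
    block_strs <- vapply(blocks, collapse, "")
    # Substituted second copies; the final residue of each variant copy is
    # always substituted, anchoring the copy in the alignment.
    copies2 <- block_strs
    sub_positions <- vector("list", nb)
    for (i in seq_len(nb)) {
      n_subs <- specs[[i]]$n_subs
      L <- specs[[i]]$length
      if (n_subs > 0L) {
        if (n_subs > L) stop("n_subs exceeds block length")
        sp <- sort(unique(c(
          if (n_subs > 1L) sample(L - 1L, n_subs - 1L) else integer(), L)))
        b2 <- chars(copies2[i])
        for (p in sp) {
          choices <- setdiff(c("A", "S", "T", "V", "L", "I", "F", "H"),
                             b2[p])
          b2[p] <- choices[sample.int(length(choices), 1L)]
        }
        copies2[i] <- collapse(b2)
        sub_positions[[i]] <- sp
      } else sub_positions[[i]] <- integer()
    }
    chunk_strs <- vapply(chunks, collapse, "")
    ref_parts <- character()
    query_parts <- character()
    spans <- vector("list", nb)
    qpos <- nchar(nterm)
    for (i in seq_len(nb + 1L)) {
      ref_parts <- c(ref_parts, chunk_strs[i])
      query_parts <- c(query_parts, chunk_strs[i])
      qpos <- qpos + nchar(chunk_strs[i])
      if (i <= nb) {
        L <- specs[[i]]$length
        ref_parts <- c(ref_parts, block_strs[i])
        query_parts <- c(query_parts, block_strs[i], copies2[i])
        copy1 <- c(qpos + 1L, qpos + L)
        copy2 <- copy1 + L
        spans[[i]] <- list(
          span = if (specs[[i]]$n_subs > 0L) copy2 else copy1,
          copy1_span = copy1, copy2_span = copy2,
          length = L, counts = specs[[i]]$counts,
          n_subs = specs[[i]]$n_subs,
          sub_positions = sub_positions[[i]])
        qpos <- qpos + 2L * L
      }
    }
    ref_rep <- collapse(ref_parts)
    query_rep <- collapse(query_parts)
    ref_prot <- paste0(SYN_SIGNAL, nterm, ref_rep, SYN_CTERM)

    ref_dna_ch <- chars(reverse_translate(ref_prot))
    # DNA-level substitutions within the repetitive-domain codons of the
    # shared (pre-duplication) sequence: the gene and its reference diverge
    # from the motif consensus at identical sites, so only the planted
    # duplication separates them. Amino-acid effects emerge via
    # translation, mirroring reality; stop-creating changes are resampled.
    if (sub_rate > 0) {
      rep_start <- 3L * (nchar(SYN_SIGNAL) + nchar(nterm)) + 1L
      rep_len_dna <- 3L * nchar(ref_rep)
      n_mut <- stats::rbinom(1L, rep_len_dna, sub_rate)
      if (n_mut > 0L) {
        at <- rep_start - 1L + sample(rep_len_dna, n_mut)
        for (p in at) {
          repeat {
            b <- sample(setdiff(c("A", "C", "G", "T"), ref_dna_ch[p]), 1L)
            old <- ref_dna_ch[p]
            ref_dna_ch[p] <- b
            cod0 <- p - (p - 1L) %% 3L
            codon <- collapse(ref_dna_ch[cod0:(cod0 + 2L)])
            if (Biostrings::GENETIC_CODE[[codon]] != "*") break
            ref_dna_ch[p] <- old
          }
        }
      }
    }
    ref_dna <- collapse(ref_dna_ch)
    # Splice the query DNA out of the (possibly mutated) reference DNA by
    # duplicating each block segment in place; a variant second copy gets
    # fresh codons at its substituted residues.
    tab <- codons_by_aa()
    q_dna_parts <- character()
    prev_end <- 0L
    cum_prev <- 0L
    for (i in seq_len(nb)) {
      L <- specs[[i]]$length
      # Block i's span in reference mature coordinates, then in ORF bp.
      rbs <- spans[[i]]$copy1_span[1] - cum_prev
      dna_s <- 3L * (nchar(SYN_SIGNAL) + rbs - 1L) + 1L
      dna_e <- dna_s + 3L * L - 1L
      copy_dna <- chars(substr(ref_dna, dna_s, dna_e))
      q_dna_parts <- c(q_dna_parts,
                       substr(ref_dna, prev_end + 1L, dna_e))
      if (specs[[i]]$n_subs > 0L) {
        b2 <- chars(copies2[i])
        for (p in sub_positions[[i]]) {
          cs <- tab[[b2[p]]]
          copy_dna[(3L * p - 2L):(3L * p)] <-
            chars(cs[sample.int(length(cs), 1L)])
        }
      }
      q_dna_parts <- c(q_dna_parts, collapse(copy_dna))
      prev_end <- dna_e
      cum_prev <- cum_prev + L
    }
    q_dna_parts <- c(q_dna_parts,
                     substr(ref_dna, prev_end + 1L, nchar(ref_dna)))
    query_dna <- collapse(q_dna_parts)
    orf_ref <- paste0(ref_dna, "TGATAG")
    orf_query <- paste0(query_dna, "TGATAG")
    ref_mature <- substr(translate_orf(orf_ref)$residues,
                         nchar(SYN_SIGNAL) + 1L, nchar(ref_prot))
    query_mature <- substr(translate_orf(orf_query)$residues,
                           nchar(SYN_SIGNAL) + 1L,
                           nchar(ref_prot) + sum(vapply(spans, `[[`, 0L,
                                                        "length")))

    list(
      record = gene_record(id, orf_query, source = "synthetic"),
      reference = gene_record(paste0(id, "_ref"), orf_ref,
                              source = "synthetic"),
      truth = list(
        seed = seed, subunit_type = subunit_type,
        signal_peptide = SYN_SIGNAL,
        nterm_len = nchar(nterm),
        rep_len_ref = nchar(ref_rep), rep_len_query = nchar(query_rep),
        cterm_len = nchar(SYN_CTERM),
        counts_main = c(tri = n_tri, hexa = n_hexa, nona = n_nona),
        insertions = spans,
        insertion = if (nb > 0L) spans[[1L]] else NULL,
        mature_ref = ref_mature, mature_query = query_mature,
        sub_rate = sub_rate
      )
    )
  })
}

# A base differing from both `avoid1` and `avoid2`, chosen deterministically.
other_base <- function(avoid1, avoid2 = "") {
  setdiff(c("A", "C", "G", "T"), c(avoid1, avoid2))[1L]
}

#' Generate a synthetic Glu-1 promoter with known ground truth
#'
#' Plants the regulatory elements (in canonical 5'->3' order, at seeded
#' offsets) into seeded random background. The per-element `plan` may
#' request substitutions at given element positions or deletion (the
#' element is simply not planted). After planting, background windows that
#' would tie or beat a planted element under [scan_elements()] -- an 8-mer
#' within 2 mismatches arises by chance about 4 times per 900 bp -- are
#' deterministically disrupted, so the generator guarantees that scanning
#' recovers exactly the planted annotation. A planted element given more
#' substitutions than its mismatch cap is expected to scan as `deleted`
#' (threshold boundary case).
#'
#' @param seed Integer seed.
#' @param plan Named list; each entry (by element name) is a list with
#'   either `deleted = TRUE` or `substitutions` = integer element positions
#'   (substituted bases are chosen deterministically) or a data frame with
#'   columns `position`, `base`.
#' @param length Total promoter length in bp (x-type promoters are 904 bp).
#' @param elements Element set, see [default_elements()].
#' @return List with `promoter` (DNA string) and `truth` (data frame:
#'   `name`, `status`, `offset`, `n_substitutions`, plus a `substitutions`
#'   list of per-element position vectors and the seed).
#' @export
generate_promoter <- function(seed, plan = list(), length = 904L,
                              elements = default_elements()) {
  ne <- nrow(elements)
  stopifnot(all(names(plan) %in% elements$name))
  planted <- !vapply(elements$name, function(nm)
    isTRUE(plan[[nm]]$deleted), TRUE)
  elen <- nchar(elements$consensus)
  need <- sum(elen[planted])
  k <- sum(planted)
  if (length < need + 5L * (k + 1L))
    stop("promoter length ", length, " too short for the planted elements")

  with_seed(seed, {
    # Random spacer layout: k+1 spacers of >= 5 bp.
    free <- length - need - 5L * (k + 1L)
    cuts <- sort(sample.int(free + 1L, k, replace = TRUE) - 1L)
    spacers <- diff(c(0L, cuts, free)) + 5L
    bg <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    offsets <- rep(NA_integer_, ne)
    pos <- 0L
    j <- 0L
    for (i in seq_len(ne)) {
      if (!planted[i]) next
      j <- j + 1L
      pos <- pos + spacers[j]
      offsets[i] <- pos + 1L
      pos <- pos + elen[i]
    }
    # Plant elements (with requested substitutions).
    subs_truth <- vector("list", ne)
    names(subs_truth) <- elements$name
    for (i in seq_len(ne)) {
      if (!planted[i]) next
      obs <- chars(elements$consensus[i])
      sp <- plan[[elements$name[i]]]$substitutions
      if (!is.null(sp)) {
        if (is.data.frame(sp)) {
          obs[sp$position] <- toupper(sp$base)
          subs_truth[[i]] <- sort(sp$position)
        } else {
          for (p in sp) obs[p] <- other_base(obs[p])
          subs_truth[[i]] <- sort(as.integer(sp))
        }
      }
      bg[offsets[i]:(offsets[i] + elen[i] - 1L)] <- obs
    }
    n_subs <- vapply(subs_truth, length, 0L)
    status <- ifelse(!planted, "deleted",
                     ifelse(n_subs > elements$max_mismatch, "deleted",
                            "found"))
    truth_df <- data.frame(
      name = elements$name, status = status,
      offset = ifelse(status == "found", offsets, NA_integer_),
      n_substitutions = ifelse(status == "found", n_subs, NA_integer_),
      stringsAsFactors = FALSE
    )
    # Spans that must not be touched by scrubbing.
    protected <- logical(length)
    for (i in which(planted))
      protected[offsets[i]:(offsets[i] + elen[i] - 1L)] <- TRUE
    # Scrub chance background hits until scanning reproduces the truth.
    for (iter in seq_len(500L)) {
      ann <- scan_elements(collapse(bg), elements)$elements
      bad <- which(ann$status != truth_df$status |
                     (ann$status == "found" &
                        (ann$offset != truth_df$offset |
                           ann$n_substitutions != truth_df$n_substitutions)))
      if (!length(bad)) break
      b <- bad[1L]
      if (ann$status[b] != "found")
        stop("planted element '", ann$name[b],
             "' not recovered; layout conflict")
      win <- ann$offset[b]:(ann$offset[b] + nchar(ann$observed[b]) - 1L)
      cons <- chars(elements$consensus[b])
      # Poison a free position that currently matches the consensus there
      # (changing an already-mismatched base would not raise the window's
      # mismatch count).
      matches <- bg[win] == cons[seq_along(win)]
      freepos <- win[!protected[win] & matches]
      if (!length(freepos))
        stop("cannot scrub chance hit overlapping planted elements")
      p <- freepos[1L]
      bg[p] <- other_base(cons[p - ann$offset[b] + 1L], bg[p])
      if (iter == 500L) stop("promoter scrubbing did not converge")
    }
    list(promoter = collapse(bg),
         truth = list(elements = truth_df, substitutions = subs_truth,
                      seed = seed))
  })
}

#' Generate an aligned sequence family evolved along a known tree
#'
#' A seeded random root sequence is evolved along the given tree with a
#' fixed number of substitutions per branch, placed at globally distinct
#' sites while any remain (so pairwise Hamming distances are additive along
#' the tree); no indels, so the leaf sequences are returned already
#' aligned.
#'
#' @param seed Integer seed.
#' @param tree An `ape::phylo` tree or a Newick string; leaf labels name
#'   the output sequences.
#' @param region_len Alignment length in bp.
#' @param mut_per_branch Substitutions per branch; scalar or vector over
#'   tree edges (in `tree$edge` row order). Must not exceed `region_len`.
#' @return List with `alignment` (named character vector) and `truth`
#'   (`tree`, per-edge mutated sites, seed).
#' @export
generate_family <- function(seed, tree, region_len = 600L,
                            mut_per_branch = 5L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  n_edge <- nrow(tree$edge)
  muts <- rep_len(as.integer(mut_per_branch), n_edge)
  if (any(muts > region_len))
    stop("mut_per_branch exceeds region_len")
  ntip <- length(tree$tip.label)
  with_seed(seed, {
    root_seq <- sample(c("A", "C", "G", "T"), region_len, replace = TRUE)
    tree2 <- ape::reorder.phylo(tree, "cladewise")
    # Map reordered edges back to input edge order for the muts vector.
    edge_key <- function(e) paste(e[, 1], e[, 2])
    muts2 <- muts[match(edge_key(tree2$edge), edge_key(tree$edge))]
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[ntip + 1L]] <- root_seq
    pool <- seq_len(region_len)
    sites_per_edge <- vector("list", n_edge)
    for (e in seq_len(n_edge)) {
      parent <- tree2$edge[e, 1L]
      child <- tree2$edge[e, 2L]
      s <- seqs[[parent]]
      m <- muts2[e]
      sites <- if (m == 0L) integer()
        else if (length(pool) >= m) {
          picked <- pool[sample.int(length(pool), m)]
          pool <- setdiff(pool, picked)
          picked
        } else sample.int(region_len, m)
      for (p in sites) s[p] <- other_base(s[p], s[p])
      seqs[[child]] <- s
      sites_per_edge[[e]] <- sort(sites)
    }
    alignment <- vapply(seq_len(ntip), function(i) collapse(seqs[[i]]), "")
    names(alignment) <- tree2$tip.label
    list(alignment = alignment,
         truth = list(tree = tree, sites_per_edge = sites_per_edge,
                      seed = seed))
  })
}
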