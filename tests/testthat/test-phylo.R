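test_that("phylo region concatenates promoter, signal and N-terminal CDS", {
  gen <- generate_subunit(41, "x")
  gp <- generate_promoter(41)
  gene <- gene_record("g1", gen$record$orf_dna, promoter_dna = gp$promoter)
  mat <- strip_signal_peptide(translate_orf(gene$orf_dna), id = "g1")
  part <- partition_domains(mat)
  reg <- extract_phylo_region(gene, mat, part)
  expect_identical(nchar(reg$sequence),
                   nchar(gp$promoter) + 3L * (21L + gen$truth$nterm_len))
  expect_true(reg$promoter_included)
  expect_true(startsWith(reg$sequence, gp$promoter))

  # Missing promoter: CDS-only region, flagged.
  gene2 <- gene_record("g2", gen$record$orf_dna)
  expect_warning(reg2 <- extract_phylo_region(gene2, mat, part),
                 "no promoter")
  expect_false(reg2$promoter_included)
  expect_identical(nchar(reg2$sequence), 3L * (21L + gen$truth$nterm_len))

  # Identical genes give identical regions.
  reg3 <- extract_phylo_region(gene, mat, part)
  expect_identical(reg3$sequence, reg$sequence)
})

test_that("p-distances use pairwise deletion and match an independent oracle", {
  expect_identical(p_distance_matrix(c(a = "ACGT", b = "ACGT"))["a", "b"], 0)
  expect_identical(p_distance_matrix(c(a = "ACGT", b = "ACGA"))["a", "b"],
                   0.25)
  # Gapped site excluded for the pair: 0 differences over 3 sites.
  expect_identical(p_distance_matrix(c(a = "AC-T", b = "ACGT"))["a", "b"], 0)

  withr::with_seed(42, {
    for (i in seq_len(10)) {
      n <- 5L
      len <- 60L
      seqs <- vapply(seq_len(n), function(k)
        paste(sample(c("A", "C", "G", "T", "-"), len, replace = TRUE,
                     prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = ""),
        "")
      names(seqs) <- paste0("s", seq_len(n))
      got <- p_distance_matrix(seqs)
      bin <- ape::as.DNAbin(do.call(rbind, lapply(seqs, ch1)))
      oracle <- as.matrix(ape::dist.dna(bin, model = "raw",
                                        pairwise.deletion = TRUE))
      expect_equal(unname(got), unname(oracle[names(seqs), names(seqs)]),
                   tolerance = 1e-12)
    }
  })

  expect_error(p_distance_matrix(c(a = "----", b = "ACGT")),
               "no comparable sites.*a.*b")
  expect_error(p_distance_matrix(c(a = "ACG", b = "ACGT")), "length")
  expect_error(p_distance_matrix(c("ACGT", "ACGT")), "names")
})

test_that("3-taxon NJ solves the three-point closed form", {
  D <- matrix(c(0, 0.3, 0.4,
                0.3, 0, 0.5,
                0.4, 0.5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  lens <- stats::setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                          tr$tip.label)
  expect_equal(unname(lens[c("a", "b", "c")]), c(0.1, 0.2, 0.3),
               tolerance = 1e-12)
})

test_that("4-taxon NJ agrees with the least-squares topology oracle", {
  withr::with_seed(7, {
    for (i in seq_len(25)) {
      # Random additive matrix from a random 4-taxon tree.
      tr0 <- ape::rtree(4, tip.label = c("a", "b", "c", "d"))
      tr0$edge.length <- stats::runif(nrow(tr0$edge), 0.05, 1)
      D <- as.matrix(ape::cophenetic.phylo(tr0))
      D <- D[c("a", "b", "c", "d"), c("a", "b", "c", "d")]
      expect_true(same_topology(neighbor_joining(D), oracle_ls_topology4(D)))
    }
  })
})

test_that("NJ reproduces additive tree metrics along its paths", {
  withr::with_seed(13, {
    for (i in seq_len(5)) {
      tr0 <- ape::rtree(6)
      tr0$edge.length <- stats::runif(nrow(tr0$edge), 0.05, 0.5)
      D <- as.matrix(ape::cophenetic.phylo(tr0))
      tr <- neighbor_joining(D)
      expect_true(same_topology(tr, tr0))
      back <- as.matrix(ape::cophenetic.phylo(tr))
      expect_equal(back[rownames(D), colnames(D)], D, tolerance = 1e-9)
      expect_true(all(tr$edge.length >= 0))
    }
  })
})

test_that("NJ handles degenerate sizes", {
  D <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  expect_warning(tr <- neighbor_joining(D), "fewer than 3")
  expect_identical(sort(tr$tip.label), c("a", "b"))
})

test_that("negative NJ branches are clamped without inflating tree length", {
  # A non-additive matrix known to produce a negative NJ branch.
  D <- matrix(c(0, 5, 9, 9,
                5, 0, 10, 10,
                9, 10, 0, 2,
                9, 10, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  raw <- ape::nj(D)
  tr <- neighbor_joining(D)
  expect_true(all(tr$edge.length >= 0))
  expect_lte(sum(tr$edge.length), sum(abs(raw$edge.length)) + 1e-9)
})

test_that("bootstrap supports are seed-deterministic and detect clean clades", {
  fam <- generate_family(61, "((a1,a2),(a3,(b1,(b2,b3))));",
                         region_len = 400, mut_per_branch = 6)
  t1 <- bootstrap_support(fam$alignment, n_reps = 100, seed = 5)
  t2 <- bootstrap_support(fam$alignment, n_reps = 100, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))

  # Two clearly separated clades: near-complete support for the split.
  fam2 <- generate_family(62, "((a1,a2,a3),(b1,b2,b3));",
                          region_len = 300, mut_per_branch = c(
                            25, 1, 1, 1, 25, 1, 1, 1))
  t3 <- bootstrap_support(fam2$alignment, n_reps = 100, seed = 5)
  sup3 <- suppressWarnings(as.numeric(t3$node.label))
  expect_gte(max(sup3, na.rm = TRUE), 95)

  expect_error(bootstrap_support(fam$alignment, n_reps = 0, seed = 1),
               "n_reps")
})

test_that("an alignment of identical sequences yields a fully unresolved metric", {
  seqs <- stats::setNames(rep("ACGTACGTACGT", 4), paste0("s", 1:4))
  tr <- suppressWarnings(bootstrap_support(seqs, n_reps = 10, seed = 1))
  expect_true(all(tr$edge.length == 0))
})
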