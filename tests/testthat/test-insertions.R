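test_that("global alignment handles identity, minimal indels and degapping", {
  aln <- global_align("PGQGQQ", "PGQGQQ")
  expect_identical(aln$aligned_query, aln$aligned_ref)
  expect_false(grepl("-", aln$aligned_query, fixed = TRUE))

  aln2 <- global_align("ACD", "AD")
  expect_identical(sum(strsplit(aln2$aligned_ref, "")[[1]] == "-"), 1L)
  expect_identical(gsub("-", "", aln2$aligned_ref), "AD")
  expect_identical(gsub("-", "", aln2$aligned_query), "ACD")
})

test_that("alignment scores equal an independent affine-gap DP oracle", {
  p <- default_align_params()
  aa <- c("G", "Q", "P", "Y", "A", "S", "T", "E")
  withr::with_seed(77, {
    for (i in seq_len(50)) {
      a <- paste(sample(aa, sample(3:12, 1), replace = TRUE), collapse = "")
      b <- paste(sample(aa, sample(3:12, 1), replace = TRUE), collapse = "")
      # Tolerance covers the aligner's single-precision gap arithmetic.
      expect_equal(global_align(a, b, p)$score, oracle_align_score(a, b, p),
                   tolerance = 1e-5, info = paste(a, b))
    }
  })
})

test_that("planted insertion blocks are detected at their exact spans", {
  gen <- generate_subunit(21, "x",
                          insertion = list(n_tri = 5, n_hexa = 15, n_nona = 4))
  ann <- annotate_synthetic(gen)
  blocks <- detect_insertions(ann$mature, ann$reference)
  expect_length(blocks, 1L)
  b <- blocks[[1]]
  expect_identical(b$length, 141L)
  expect_identical(b$query_span, gen$truth$insertion$span)
  expect_identical(c(b$census$n_tri, b$census$n_hexa, b$census$n_nona),
                   c(5L, 15L, 4L))
  expect_identical(b$census$n_unassigned_residues, 0L)

  # Identical query and reference: nothing to report.
  expect_length(detect_insertions(ann$reference, ann$reference), 0L)
})

test_that("two planted blocks are both recovered with min_block filtering", {
  gen <- generate_subunit(22, "y",
                          insertion = list(list(n_tri = 0, n_hexa = 5, n_nona = 5),
                                           list(n_tri = 0, n_hexa = 7, n_nona = 7)))
  ann <- annotate_synthetic(gen)
  blocks <- detect_insertions(ann$mature, ann$reference, min_block = 30)
  expect_length(blocks, 2L)
  expect_identical(vapply(blocks, `[[`, 0L, "length"), c(75L, 105L))
  expect_identical(blocks[[1]]$query_span, gen$truth$insertions[[1]]$span)
  expect_identical(blocks[[2]]$query_span, gen$truth$insertions[[2]]$span)
  # A min_block above the smaller block hides it.
  expect_length(detect_insertions(ann$mature, ann$reference, min_block = 80),
                1L)
})

test_that("insertions reappear as query gaps when the comparison is reversed", {
  gen <- generate_subunit(23, "x",
                          insertion = list(n_tri = 5, n_hexa = 15, n_nona = 4))
  ann <- annotate_synthetic(gen)
  aln <- global_align(ann$reference$residues, ann$mature$residues)
  gaps <- strsplit(aln$aligned_query, "")[[1]] == "-"
  runs <- rle(gaps)
  expect_identical(runs$lengths[runs$values], 141L)
})

test_that("subunit type mismatch is rejected", {
  gx <- annotate_synthetic(generate_subunit(24, "x"))
  gy <- annotate_synthetic(generate_subunit(24, "y"))
  expect_error(detect_insertions(gx$mature, gy$mature), "type mismatch")
})

test_that("tandem duplication verification scores perfect and variant copies", {
  gen <- generate_subunit(25, "x",
                          insertion = list(n_tri = 5, n_hexa = 15, n_nona = 4))
  ann <- annotate_synthetic(gen)
  b <- detect_insertions(ann$mature, ann$reference)[[1]]
  ev <- verify_tandem_duplication(ann$mature, b, ann$partition)
  expect_equal(ev$identity_pct, 100)
  expect_length(ev$variant_positions, 0L)
  expect_identical(ev$flank, "downstream")

  gen3 <- generate_subunit(26, "y",
                           insertion = list(n_tri = 0, n_hexa = 7, n_nona = 7,
                                            n_subs = 3))
  ann3 <- annotate_synthetic(gen3)
  b3 <- detect_insertions(ann3$mature, ann3$reference)[[1]]
  ev3 <- verify_tandem_duplication(ann3$mature, b3, ann3$partition)
  expect_equal(ev3$identity_pct, 100 * (105 - 3) / 105)
  expect_identical(ev3$variant_positions,
                   gen3$truth$insertion$sub_positions)
  expect_identical(ev3$flank, "upstream")
})

test_that("a shuffled block shows only background identity to its flanks", {
  gen <- generate_subunit(27, "x",
                          insertion = list(n_tri = 5, n_hexa = 15, n_nona = 4))
  ann <- annotate_synthetic(gen)
  b <- detect_insertions(ann$mature, ann$reference)[[1]]
  frag <- strsplit(b$fragment, "")[[1]]
  idents <- withr::with_seed(99, vapply(seq_len(100), function(i) {
    shuf <- b
    shuf$fragment <- paste(sample(frag), collapse = "")
    suppressWarnings(
      verify_tandem_duplication(ann$mature, shuf, ann$partition)$identity_pct)
  }, 0))
  # Empirical null of the alignment-identity statistic on this Q/G-rich
  # alphabet sits near 42%; a true tandem copy scores at or near 100%.
  expect_lt(mean(idents), 45)
  expect_lt(max(idents), 60)
})
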