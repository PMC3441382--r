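test_that("consensus comparison lists substitution positions", {
  # E motif of the 1S-type x alleles vs the consensus: positions 6 and 7.
  subs <- compare_to_consensus("TGTAAATC", "TGTAACCC")
  expect_identical(subs$position, c(6L, 7L))
  expect_identical(subs$consensus_base, c("C", "C"))
  expect_identical(subs$observed_base, c("A", "T"))

  expect_identical(nrow(compare_to_consensus("TTATCA", "TTATCA")), 0L)

  # Start motif variant: one substitution at position 2.
  subs2 <- compare_to_consensus("TCATCA", "TTATCA")
  expect_identical(subs2$position, 2L)

  expect_error(compare_to_consensus("TTA", "TTAT"), "lengths differ")
})

test_that("a promoter with all six perfect elements is fully annotated", {
  gp <- generate_promoter(301)
  ann <- scan_elements(gp$promoter)
  expect_identical(ann$elements$status, rep("found", 6L))
  expect_identical(ann$elements$offset, gp$truth$elements$offset)
  expect_identical(ann$elements$n_substitutions, rep(0L, 6L))
  expect_identical(ann$elements$name, default_elements()$name)
  # Found elements do not overlap and appear in 5'->3' order.
  ends <- ann$elements$offset + nchar(ann$elements$observed) - 1L
  expect_true(all(diff(ann$elements$offset) > 0))
  expect_true(all(utils::head(ends, -1) < utils::tail(ann$elements$offset, -1)))
})

test_that("planted substitutions and deletions are reported exactly", {
  gp <- generate_promoter(302, plan = list(
    E_motif = list(substitutions = c(6L, 7L)),
    partial_enhancer = list(deleted = TRUE),
    start_motif = list(substitutions = 2L)
  ), length = 845L)
  ann <- scan_elements(gp$promoter)
  df <- ann$elements
  expect_identical(df$status[df$name == "partial_enhancer"], "deleted")
  expect_identical(df$status[df$name != "partial_enhancer"], rep("found", 5L))
  expect_identical(ann$substitutions$E_motif$position, c(6L, 7L))
  expect_identical(ann$substitutions$start_motif$position, 2L)
  expect_identical(df$offset[df$status == "found"],
                   gp$truth$elements$offset[df$status == "found"])
  # The complete enhancer is intact even though its core equals the deleted
  # partial enhancer.
  expect_identical(df$n_substitutions[df$name == "enhancer"], 0L)
})

test_that("an element mutated past its mismatch cap scans as deleted", {
  gp <- generate_promoter(303, plan = list(
    N_motif = list(substitutions = c(2L, 4L, 7L))  # cap is 2
  ))
  expect_identical(gp$truth$elements$status[2], "deleted")
  ann <- scan_elements(gp$promoter)
  expect_identical(ann$elements$status[2], "deleted")
  expect_identical(ann$elements$status[-2], rep("found", 5L))
})

test_that("re-scanning observed sequences reproduces the substitution lists", {
  gp <- generate_promoter(304, plan = list(
    E_motif = list(substitutions = 3L),
    TATA_box = list(substitutions = c(1L, 5L))
  ))
  ann <- scan_elements(gp$promoter)
  el <- default_elements()
  for (i in seq_len(nrow(ann$elements))) {
    row <- ann$elements[i, ]
    if (row$status != "found" || !is.na(row$gap_position)) next
    again <- compare_to_consensus(row$observed, el$consensus[i])
    expect_identical(again, ann$substitutions[[row$name]], info = row$name)
    expect_identical(nrow(again), row$n_substitutions)
  }
})

test_that("annotation is invariant to upstream padding", {
  gp <- generate_promoter(305)
  ann <- scan_elements(gp$promoter)
  pad <- withr::with_seed(306,
    paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = ""))
  ann2 <- scan_elements(paste0(pad, gp$promoter))
  expect_identical(ann2$elements$status, ann$elements$status)
  expect_identical(ann2$elements$n_substitutions,
                   ann$elements$n_substitutions)
  expect_identical(ann2$elements$offset, ann$elements$offset + 200L)
})

test_that("a 1 bp deletion inside the enhancer is a gapped hit, not a loss", {
  gp <- generate_promoter(307)
  off <- gp$truth$elements$offset[4]
  # Drop the 7th enhancer base (the C after GTTTTG, as in the 1Bx7 allele).
  prom <- paste0(substr(gp$promoter, 1, off + 5L),
                 substr(gp$promoter, off + 7L, nchar(gp$promoter)))
  ann <- scan_elements(prom)
  row <- ann$elements[ann$elements$name == "enhancer", ]
  expect_identical(row$status, "found")
  expect_false(is.na(row$gap_position))
  expect_identical(row$offset, off)
  expect_identical(nchar(row$observed), 37L)
  expect_identical(row$n_substitutions, 0L)
  # Downstream elements are still found, one base earlier.
  expect_identical(ann$elements$status, rep("found", 6L))
  expect_identical(ann$elements$offset[5:6],
                   gp$truth$elements$offset[5:6] - 1L)
})

test_that("degenerate promoters are rejected", {
  expect_error(scan_elements("TGTAACCC"), "shorter than the longest")
})
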