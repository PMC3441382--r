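test_that("signal peptide stripping anchors on the mature-start signature", {
  gen <- generate_subunit(3, "x")
  prot <- translate_orf(gen$record$orf_dna)
  mat <- strip_signal_peptide(prot, id = "s")
  expect_identical(mat$signal_peptide, gen$truth$signal_peptide)
  expect_true(startsWith(mat$residues, "EGEAS"))
  # Concatenation reconstructs the full translation.
  expect_identical(paste0(mat$signal_peptide, mat$residues), prot$residues)

  # Already-mature input: zero-length signal peptide.
  mat2 <- strip_signal_peptide(mat$residues, id = "m")
  expect_identical(mat2$signal_peptide, "")
  expect_identical(mat2$residues, mat$residues)

  # Two occurrences: leftmost wins.
  two <- paste0("MKL", "EGEAS", "AAA", "EGEAS", "GQLQCER")
  mat3 <- strip_signal_peptide(two, id = "t")
  expect_identical(mat3$signal_peptide, "MKL")

  # Signature absent: warning, nothing stripped, unknown type.
  expect_warning(mat4 <- strip_signal_peptide("MKLAAARRR", id = "u"),
                 "not found")
  expect_identical(mat4$status, "no_signature")
  expect_identical(mat4$subunit_type, "unknown")
  expect_identical(mat4$residues, "MKLAAARRR")
})

test_that("subunit typing uses residue 6 with an N-terminal-length fallback", {
  expect_identical(classify_subunit_type("EGEASGQLQCERAB"), "x")
  expect_identical(classify_subunit_type("EGEASEQLQCERAB"), "x")
  expect_identical(classify_subunit_type("EGEASRQLQCERAB"), "y")
  expect_identical(classify_subunit_type("EGEASKQLQCERAB"), "y")
  expect_identical(classify_subunit_type("EGEAS"), "unknown")

  # Residue 6 uninformative: fall back to the 104-residue y N-terminal.
  gen <- generate_subunit(5, "y")
  mat <- strip_signal_peptide(translate_orf(gen$record$orf_dna), id = "y")
  res <- mat$residues
  substr(res, 6, 6) <- "X"
  expect_identical(classify_subunit_type(res), "y")

  genx <- generate_subunit(5, "x")
  matx <- strip_signal_peptide(translate_orf(genx$record$orf_dna), id = "x")
  resx <- matx$residues
  substr(resx, 6, 6) <- "X"
  expect_identical(classify_subunit_type(resx), "x")
})

test_that("domain partition recovers planted architecture and tiles the sequence", {
  for (seed in 1:4) {
    for (type in c("x", "y")) {
      gen <- generate_subunit(seed, type)
      mat <- strip_signal_peptide(translate_orf(gen$record$orf_dna),
                                  id = "s")
      part <- partition_domains(mat)
      expect_identical(span_lengths <- c(
        glutannot:::span_len(part$n_terminal),
        glutannot:::span_len(part$repetitive),
        glutannot:::span_len(part$c_terminal)),
        c(gen$truth$nterm_len, gen$truth$rep_len_query, 42L))
      expect_identical(sum(span_lengths), nchar(mat$residues))
      expect_identical(part$c_terminal[2], nchar(mat$residues))
    }
  }
})

test_that("a short repeat-free mature sequence has an empty repetitive domain", {
  m <- paste0("EGEASRELKNERAELQERAKELQERAKELQERAKELQERAKEL")  # 43 aa
  expect_identical(nchar(m), 43L)
  expect_warning(part <- partition_domains(m), "no repeat onset")
  expect_null(part$repetitive)
  expect_identical(part$n_terminal, c(1L, 1L))
  expect_identical(part$c_terminal, c(2L, 43L))
  expect_error(partition_domains("EGEAS"), "too short")
})

test_that("cysteine census matches planted counts and the naive total", {
  genx <- generate_subunit(9, "x")
  mx <- strip_signal_peptide(translate_orf(genx$record$orf_dna), id = "x")
  px <- partition_domains(mx)
  cx <- cysteine_census(mx, px)
  expect_identical(c(cx$n_nterm, cx$n_rep, cx$n_cterm, cx$n_total),
                   c(3L, 0L, 1L, 4L))
  expect_true(cx$conforms)

  geny <- generate_subunit(9, "y")
  my <- strip_signal_peptide(translate_orf(geny$record$orf_dna), id = "y")
  py <- partition_domains(my)
  cy <- cysteine_census(my, py)
  expect_identical(c(cy$n_nterm, cy$n_rep, cy$n_cterm, cy$n_total),
                   c(5L, 1L, 1L, 7L))
  expect_true(cy$conforms)

  # Census total always equals the naive whole-sequence count.
  for (m in list(mx, my))
    expect_identical(cysteine_census(m, partition_domains(m))$n_total,
                     sum(strsplit(m$residues, "")[[1]] == "C"))

  # x-type with one extra repetitive cysteine (the 1Dx5 pattern) is a known
  # pattern, not a deviation.
  resx <- mx$residues
  hexa_at <- regexpr("PGQGQQ", resx, fixed = TRUE)
  substr(resx, hexa_at + 4L, hexa_at + 4L) <- "C"
  mx5 <- mx
  mx5$residues <- resx
  cx5 <- cysteine_census(mx5, partition_domains(mx5))
  expect_identical(c(cx5$n_nterm, cx5$n_rep, cx5$n_cterm), c(3L, 1L, 1L))
  expect_identical(cx5$n_total, 5L)
  expect_true(cx5$conforms)

  # No cysteines at all: zero census, flagged non-conforming.
  m0 <- mx
  m0$residues <- gsub("C", "S", mx$residues, fixed = TRUE)
  c0 <- cysteine_census(m0, partition_domains(m0))
  expect_identical(c0$n_total, 0L)
  expect_false(c0$conforms)
})
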