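test_that("construction validates and normalises the coding sequence", {
  expect_error(CodingSequence("ATGA"), "multiple of 3")
  expect_error(CodingSequence("ATGNNN"), "other than A/C/G/T")
  expect_error(CodingSequence(""), "empty")
  expect_warning(CodingSequence("AAAGGG"), "ATG")
  # trailing stop is trimmed, internal stop kept for translate to reject
  cds <- CodingSequence("ATGAAATAA")
  expect_identical(as.character(cds@seq), "ATGAAA")
  expect_true(cds@trimmedStop)
  expect_error(CodingSequence("ATGAAAAAA", leaderLength = 3), "leader")
})

test_that("translation follows the standard code and rejects broken frames", {
  expect_identical(translateCds(CodingSequence("ATGAAA")), "MK")
  expect_identical(translateCds(CodingSequence("ATGTAA")), "M")
  expect_error(translateCds(CodingSequence("ATGTAAAAA")),
               "premature stop")
  for (seed in 1:5) {
    s <- random_cds_string(100, seed)
    expect_identical(translateCds(CodingSequence(s)), oracle_translate(s))
  }
})

test_that("toy enumeration matches the hand-computed census and labels", {
  ms <- enumerateMissense(CodingSequence("ATGAAA"))
  expect_setequal(mutations(ms)$label,
                  c("M1L", "M1V", "M1K", "M1T", "M1R", "M1I",
                    "K2Q", "K2E", "K2I", "K2T", "K2R", "K2N"))
  cen <- as.data.frame(census(ms))
  expect_identical(cen$n_total, 18L)
  expect_identical(cen$n_silent, 1L)
  expect_identical(cen$n_nonsense, 1L)
  expect_identical(cen$n_missense_unique, 12L)

  # leader filter removes codon-1 missense changes
  ms1 <- enumerateMissense(CodingSequence("ATGAAA", leaderLength = 1))
  expect_setequal(mutations(ms1)$label,
                  c("K2Q", "K2E", "K2I", "K2T", "K2R", "K2N"))
  expect_identical(as.data.frame(census(ms1))$n_leader_excluded, 9L)
})

test_that("census categories partition 3L substitutions on random cDNAs", {
  for (seed in 1:8) {
    n_codons <- sample(5:40, 1)
    cds <- CodingSequence(random_cds_string(n_codons, seed),
                          leaderLength = sample(0:2, 1))
    cen <- as.data.frame(census(enumerateMissense(cds)))
    expect_identical(cen$n_total, 3L * 3L * n_codons)
    expect_identical(cen$n_silent + cen$n_nonsense + cen$n_leader_excluded +
                       cen$n_missense_raw, cen$n_total)
    expect_lte(cen$n_missense_unique, cen$n_missense_raw)
  }
})

test_that("enumeration agrees with the brute-force string-mutation oracle", {
  for (seed in 1:6) {
    leader <- seed %% 3
    s <- random_cds_string(sample(4:20, 1), seed + 100)
    ms <- enumerateMissense(CodingSequence(s, leaderLength = leader))
    oracle <- oracle_enumerate(s, leader)
    expect_identical(sort(unique(mutations(ms)$label)), oracle$labels)
    cen <- as.data.frame(census(ms))
    expect_identical(cen$n_silent, unname(oracle$census["silent"]))
    expect_identical(cen$n_nonsense, unname(oracle$census["nonsense"]))
    expect_identical(cen$n_leader_excluded, unname(oracle$census["leader"]))
    expect_identical(cen$n_missense_raw, unname(oracle$census["missense"]))
  }
})

test_that("enumeration is deterministic and mutations are self-consistent", {
  cds <- CodingSequence(random_cds_string(30, 7))
  a <- enumerateMissense(cds)
  b <- enumerateMissense(cds)
  expect_identical(mutations(a), mutations(b))

  tab <- mutations(a)
  prot <- strsplit(translateCds(cds), "")[[1]]
  expect_identical(tab$ref_aa, prot[tab$protein_position])
  expect_identical(tab$label,
                   paste0(tab$ref_aa, tab$protein_position, tab$alt_aa))
  # cdna position falls inside the codon of the protein position
  expect_true(all((tab$cdna_position - 1) %/% 3 + 1 == tab$protein_position))
  expect_true(all(tab$ref_aa != tab$alt_aa))
})

test_that("duplicate protein mutations collapse but provenance is kept on request", {
  cds <- CodingSequence("ATGAAA")
  full <- mutations(enumerateMissense(cds, collapse = FALSE))
  collapsed <- mutations(enumerateMissense(cds, collapse = TRUE))
  expect_gt(nrow(full), nrow(collapsed))
  expect_identical(sort(unique(full$label)), sort(collapsed$label))
  expect_false(anyDuplicated(collapsed$label) > 0)
  # the raw table keeps distinct nucleotide changes for the same mutation
  expect_gt(sum(full$label == "K2N"), 1L)
})
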