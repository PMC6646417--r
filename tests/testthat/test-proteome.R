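test_that("variant application handles substitutions and left-anchored indels", {
  cds <- "ATGGCTTAA"
  expect_equal(apply_variants_to_cds(cds, tibble::tibble(cds_pos = 5L, ref = "C", alt = "A")),
               "ATGGATTAA")
  expect_equal(apply_variants_to_cds(cds, tibble::tibble(cds_pos = 4L, ref = "G", alt = "GA")),
               "ATGGACTTAA")
  expect_equal(apply_variants_to_cds(cds, tibble::tibble(cds_pos = 4L, ref = "GCT", alt = "G")),
               "ATGGTAA")
  expect_equal(apply_variants_to_cds(cds, tibble::tibble(cds_pos = integer(0),
                                                         ref = character(0),
                                                         alt = character(0))), cds)
})

test_that("variant application rejects reference mismatches and overlaps", {
  cds <- "ATGGCTTAA"
  expect_error(
    apply_variants_to_cds(cds, tibble::tibble(cds_pos = 5L, ref = "G", alt = "A"), "TX9"),
    "TX9.*position 5"
  )
  expect_error(
    apply_variants_to_cds(cds, tibble::tibble(cds_pos = c(4L, 5L),
                                              ref = c("GCT", "C"), alt = c("G", "A"))),
    "overlapping"
  )
  expect_error(
    apply_variants_to_cds(cds, tibble::tibble(cds_pos = 9L, ref = "AAA", alt = "A")),
    "outside CDS bounds"
  )
})

test_that("translation uses the standard code, stops at stops, drops partial codons, and maps N to X", {
  expect_equal(translate_cds("ATGGCTTAA"), "MA")
  expect_equal(translate_cds("ATGGACTTAA"), "MDL")
  expect_equal(translate_cds("ATGTAAGCT"), "M")
  expect_equal(translate_cds("ATGAANGGG"), "MXG")
  expect_equal(translate_cds("AT"), "")
})

test_that("proteome construction follows the two-pseudo-haplotype rule", {
  ref <- make_reference("T1", paste0("ATG", strrep("GCA", 20), "TAA"))
  # no variants: reference protein only
  v0 <- make_variants(transcript_id = character(0), cds_pos = integer(0),
                      ref = character(0), alt = character(0), effect = character(0),
                      sample_id = character(0), dosage = integer(0))
  p0 <- build_individual_proteome("S1", ref, v0)
  expect_equal(p0$proteins$T1, translate_cds(ref$cds))

  # one het missense: reference + variant product
  v1 <- make_variants(transcript_id = "T1", cds_pos = 7L, ref = "G", alt = "T",
                      effect = "missense", sample_id = "S1", dosage = 1L)
  p1 <- build_individual_proteome("S1", ref, v1)
  expect_length(p1$proteins$T1, 2L)
  expect_true(translate_cds(ref$cds) %in% p1$proteins$T1)

  # one hom-alt missense: variant product only
  v2 <- v1; v2$dosage <- 2L
  p2 <- build_individual_proteome("S1", ref, v2)
  expect_length(p2$proteins$T1, 1L)
  expect_false(translate_cds(ref$cds) %in% p2$proteins$T1)

  # two hets co-located on H2: reference survives, both-variant product on H2
  v3 <- make_variants(transcript_id = "T1", cds_pos = c(7L, 13L), ref = "G", alt = "T",
                      effect = "missense", sample_id = "S1", dosage = 1L)
  p3 <- build_individual_proteome("S1", ref, v3)
  expect_length(p3$proteins$T1, 2L)
  expect_true(translate_cds(ref$cds) %in% p3$proteins$T1)
})

test_that("a single in-frame missense changes exactly one residue", {
  set.seed(21)
  for (i in 1:25) {
    cds <- random_micro_cds(sample(12:25, 1L))
    n_codons <- nchar(cds) %/% 3L
    codon <- sample(2:(n_codons - 1L), 1L)
    pos <- 3L * (codon - 1L) + sample(1:3, 1L)
    ref_b <- substr(cds, pos, pos)
    alt_b <- sample(setdiff(BASES, ref_b), 1L)
    mut <- translate_cds(apply_variants_to_cds(
      cds, tibble::tibble(cds_pos = pos, ref = ref_b, alt = alt_b)))
    wt <- translate_cds(cds)
    if (nchar(mut) == nchar(wt)) {
      diffs <- sum(strsplit(mut, "")[[1]] != strsplit(wt, "")[[1]])
      expect_lte(diffs, 1L)
    } else {
      # premature stop introduced: truncated product is a prefix plus <=1 change
      expect_lt(nchar(mut), nchar(wt))
    }
  }
})

test_that("a frameshift preserves the reference protein prefix before the indel", {
  set.seed(22)
  for (i in 1:25) {
    cds <- random_micro_cds(sample(12:25, 1L))
    n_codons <- nchar(cds) %/% 3L
    codon <- sample(3:(n_codons - 2L), 1L)
    anchor <- 3L * (codon - 1L)
    ins <- paste(sample(BASES, sample(c(1L, 2L), 1L), replace = TRUE), collapse = "")
    mut <- translate_cds(apply_variants_to_cds(
      cds, tibble::tibble(cds_pos = anchor, ref = substr(cds, anchor, anchor),
                          alt = paste0(substr(cds, anchor, anchor), ins))))
    wt <- translate_cds(cds)
    prefix_len <- codon - 2L   # residues fully upstream of the anchor codon
    expect_equal(substr(mut, 1L, prefix_len), substr(wt, 1L, prefix_len))
  }
})

test_that("proteome construction matches the character-level rebuild oracle", {
  set.seed(23)
  for (i in 1:40) {
    inst <- random_micro_instance()
    for (s in c("D", "R")) {
      got <- build_individual_proteome(s, inst$reference, inst$variants)
      want <- oracle_proteome(s, inst$reference, inst$variants)
      for (tx in names(want)) {
        expect_setequal(got$proteins[[tx]], want[[tx]])
      }
    }
  }
})
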