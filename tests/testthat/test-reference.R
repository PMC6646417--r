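write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))), path)
  path
}

test_that("CDS reading applies the ATG and minimum-length filters", {
  p <- write_fasta(c(
    "T1 gene:G1" = paste0("ATG", strrep("GCT", 19)),   # 60 nt, ATG
    "T2 gene:G2" = paste0("GTG", strrep("GCT", 19)),   # no ATG
    "T3 gene:G3" = paste0("ATG", strrep("GCT", 9))     # 30 nt
  ))
  suppressMessages(ref <- read_cds_fasta(p))
  expect_equal(ref$transcript_id, "T1")
  expect_equal(ref$gene_id, "G1")

  # boundary: exactly 50 nt starting ATG is kept ("at least 50")
  p2 <- write_fasta(c("T50" = paste0("ATG", strrep("A", 47))))
  ref2 <- read_cds_fasta(p2)
  expect_equal(nchar(ref2$cds), 50L)
  expect_equal(ref2$gene_id, "T50")  # no gene token -> transcript id reused
})

test_that("CDS reading rejects malformed input and empty files warn", {
  p <- write_fasta(c("T1" = strrep("ATGGCA", 10), "T1 gene:G9" = strrep("ATGGCA", 10)))
  expect_error(read_cds_fasta(p), "duplicate transcript_id.*T1")

  p2 <- write_fasta(c("T1" = paste0("ATGQQ", strrep("A", 46))))
  expect_error(read_cds_fasta(p2), "outside A/C/G/T/N")

  p3 <- tempfile(fileext = ".fa"); file.create(p3)
  expect_warning(ref <- read_cds_fasta(p3), "no records")
  expect_equal(nrow(ref), 0L)
})

test_that("FASTA write/read round-trips a reference exactly", {
  ref <- make_reference(c("TX1", "TX2"),
                        c(strrep("ATGGCATCA", 8), strrep("ATGAAACCC", 9)),
                        genes = c("GA", "GB"))
  p <- tempfile(fileext = ".fa")
  write_cds_fasta(ref, p)
  back <- read_cds_fasta(p)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(ref))
})

write_test_vcf <- function(records, samples = c("S1", "S2"),
                           path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"ann\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"gq\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", samples),
          collapse = "\t"),
    records
  ), path)
  path
}

test_that("annotated VCF parsing expands per transcript and drops non-coding effects", {
  rec <- c(
    "T1\t5\t.\tC\tA\t.\tPASS\tANN=T1|missense|5|C|A\tGT:DP:GQ\t0/1:30:99\t1/1:25:80",
    "T2\t8\t.\tG\tT\t.\tPASS\tANN=T2|synonymous_variant|8|G|T\tGT:DP:GQ\t0/1:30:99\t0/0:30:99",
    "T3\t4\t.\tG\tGA\t.\tPASS\tANN=T3|insertion|4|G|GA,T4|frameshift|4|G|GA\tGT:DP:GQ\t0/1:30:99\t./.:.:."
  )
  v <- read_annotated_vcf(write_test_vcf(rec), samples = c("S1", "S2"))
  expect_s3_class(v, "variant_calls")
  # record 1: one annotation x 2 samples; record 2 dropped; record 3: 2 annotations x 2
  expect_equal(nrow(v), 6L)
  expect_setequal(unique(v$transcript_id), c("T1", "T3", "T4"))
  m <- v[v$transcript_id == "T1", ]
  expect_equal(sort(m$dosage), c(1L, 2L))
  expect_equal(m$dp[m$sample_id == "S1"], 30)
  expect_true(all(v$missing[v$sample_id == "S2" & v$transcript_id %in% c("T3", "T4")]))
})

test_that("VCF parsing errors on absent samples and warns on missing annotations", {
  rec <- "T1\t5\t.\tC\tA\t.\tPASS\t.\tGT:DP:GQ\t0/1:30:99\t1/1:25:80"
  p <- write_test_vcf(rec)
  expect_error(read_annotated_vcf(p, samples = c("S1", "S9")), "S9")
  expect_warning(v <- read_annotated_vcf(p, samples = "S1"), "without ANN")
  expect_equal(nrow(v), 0L)
})

test_that("genotype hard filter sets failing genotypes missing, drops dead variants, and is idempotent", {
  v <- make_variants(
    transcript_id = c("T1", "T1", "T2", "T2"),
    cds_pos = c(5L, 5L, 9L, 9L),
    ref = "C", alt = "A", effect = "missense",
    sample_id = c("S1", "S2", "S1", "S2"),
    dosage = c(1L, 2L, 1L, 1L),
    dp = c(10, 30, 5, 9),
    gq = c(99, 99, 99, 99)
  )
  thr <- quality_thresholds(dp_min = 15, gq_min = 20)
  f <- genotype_quality_filter(v, thr)
  # T2 fails in both samples -> removed entirely
  expect_setequal(unique(f$transcript_id), "T1")
  expect_true(f$missing[f$sample_id == "S1"])
  expect_true(is.na(f$dosage[f$sample_id == "S1"]))
  expect_false(f$missing[f$sample_id == "S2"])
  expect_identical(genotype_quality_filter(f, thr), f)

  # all passing -> identity
  ok <- make_variants(transcript_id = "T1", cds_pos = 5L, ref = "C", alt = "A",
                      effect = "missense", sample_id = c("S1", "S2"),
                      dosage = c(1L, 0L), dp = 40, gq = 99)
  expect_identical(genotype_quality_filter(ok, thr), ok)
})

test_that("surviving genotype count is monotone in the thresholds", {
  set.seed(11)
  v <- make_variants(
    transcript_id = rep(paste0("T", 1:20), each = 2L),
    cds_pos = rep(5L, 40L), ref = "C", alt = "A", effect = "missense",
    sample_id = rep(c("S1", "S2"), 20L),
    dosage = sample(0:2, 40L, replace = TRUE),
    dp = sample(0:50, 40L, replace = TRUE),
    gq = sample(0:99, 40L, replace = TRUE)
  )
  survivors <- function(dp, gq) {
    f <- genotype_quality_filter(v, quality_thresholds(dp, gq))
    sum(!f$missing)
  }
  for (i in 1:20) {
    t1 <- c(sample(0:30, 1), sample(0:60, 1))
    t2 <- t1 + c(sample(0:20, 1), sample(0:30, 1))
    expect_gte(survivors(t1[1], t1[2]), survivors(t2[1], t2[2]))
  }
})

test_that("non-synonymous gate keeps the whitelist and warns on unknown effects", {
  v <- make_variants(
    transcript_id = c("T1", "T2", "T3"), cds_pos = 5L, ref = "C", alt = "A",
    effect = c("missense", "frameshift", "weird_effect"),
    sample_id = "S1", dosage = 1L
  )
  expect_warning(out <- select_nonsynonymous(v), "weird_effect")
  expect_setequal(out$effect, c("missense", "frameshift"))
  empty <- v[0, ]
  expect_equal(nrow(select_nonsynonymous(empty)), 0L)
})
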