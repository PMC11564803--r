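test_that("MD/CIGAR reconstruction recovers the expected events", {
  # perfect match
  expect_equal(nrow(reconstruct_mismatches(
    list(pos = 1L, cigar = "4M", md = "4", seq = "ACGT", qual = "IIII"))), 0L)
  # single substitution
  mm <- reconstruct_mismatches(
    list(pos = 1L, cigar = "4M", md = "2G1", seq = "ACTT", qual = "III5"))
  expect_equal(mm$gpos, 3L)
  expect_equal(mm$ref, "G")
  expect_equal(mm$alt, "T")
  expect_equal(mm$class, "SBS")
  expect_equal(mm$bq, 40L)
  # one insertion, zero substitutions
  mm <- reconstruct_mismatches(
    list(pos = 10L, cigar = "2M1I2M", md = "4", seq = "ACTGT",
         qual = "IIIII"))
  expect_equal(mm$class, "INS")
  expect_equal(mm$alt, "T")
  expect_equal(mm$gpos, 11L)
  # deletion carries the deleted reference bases
  mm <- reconstruct_mismatches(
    list(pos = 10L, cigar = "3M2D3M", md = "3^CA3", seq = "ACGTTT",
         qual = "IIIIII"))
  expect_equal(mm$class, "DEL")
  expect_equal(mm$ref, "CA")
  expect_equal(mm$gpos, 13L)
  # soft clips contribute nothing and shift read offsets
  mm <- reconstruct_mismatches(
    list(pos = 5L, cigar = "2S3M", md = "1A1", seq = "GGACT",
         qual = "IIIII"))
  expect_equal(mm$gpos, 6L)
  expect_equal(mm$read_off, 4L)
  expect_equal(mm$alt, "C")
})

test_that("adjacent substitutions merge into doublets; long runs are dropped", {
  mm <- reconstruct_mismatches(
    list(pos = 1L, cigar = "6M", md = "1CC3", seq = "ATTGGG",
         qual = "IIIIII"))
  expect_equal(mm$class, "DBS")
  expect_equal(mm$ref, "CC")
  expect_equal(mm$alt, "TT")
  mm3 <- reconstruct_mismatches(
    list(pos = 1L, cigar = "7M", md = "1CCC3", seq = "ATTTGGG",
         qual = "IIIIIII"))
  expect_equal(nrow(mm3), 0L)
})

test_that("malformed and missing tags raise typed errors naming the read", {
  expect_error(
    reconstruct_mismatches(list(pos = 1L, cigar = "4M", md = NA,
                                seq = "ACGT", qual = "IIII",
                                qname = "r1")),
    class = "plasmasig_missing_tag")
  expect_error(
    reconstruct_mismatches(list(pos = 1L, cigar = "4M", md = "9",
                                seq = "ACGT", qual = "IIII",
                                qname = "r1")),
    class = "plasmasig_malformed_record")
  expect_error(
    reconstruct_mismatches(list(pos = 1L, cigar = "4M", md = "1",
                                seq = "ACGT", qual = "IIII",
                                qname = "r1")),
    class = "plasmasig_malformed_record")
  err <- tryCatch(
    reconstruct_mismatches(list(pos = 1L, cigar = "4M", md = "9",
                                seq = "ACGT", qual = "IIII",
                                qname = "readX")),
    error = function(e) conditionMessage(e))
  expect_match(err, "readX")
  # MD-derived reference must agree with a supplied reference window
  expect_error(
    reconstruct_mismatches(list(pos = 1L, cigar = "4M", md = "2G1",
                                seq = "ACTT", qual = "IIII"),
                           reference_window = "ACTT"),
    class = "plasmasig_malformed_record")
})

test_that("reconstruction equals the brute-force alignment oracle on fuzzed fragments", {
  set.seed(303)
  ref <- paste(sample(BASES, 200, replace = TRUE), collapse = "")
  rng <- function(n) sample.int(n, 1)
  for (i in 1:1000) {
    fz <- fuzz_read(ref, pos = 20L + rng(60L), rng = rng)
    got <- reconstruct_mismatches(fz[c("pos", "cigar", "md", "seq", "qual")])
    want <- merge_truth(fz$truth)
    got <- as.data.frame(got[order(got$gpos, got$class),
                             c("gpos", "ref", "alt", "class")])
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want[, c("gpos", "ref", "alt", "class")],
                 info = paste("case", i, fz$cigar, fz$md))
  }
})

test_that("compute_md reproduces tags consistent with reconstruction", {
  set.seed(304)
  ref <- paste(sample(BASES, 150, replace = TRUE), collapse = "")
  rng <- function(n) sample.int(n, 1)
  for (i in 1:100) {
    fz <- fuzz_read(ref, pos = 10L + rng(40L), rng = rng)
    md2 <- compute_md(fz$seq, fz$cigar,
                      substr(ref, fz$pos, nchar(ref)))
    expect_equal(md2, fz$md, info = fz$cigar)
  }
})

test_that("indels left-align to their canonical representation", {
  gs <- "GGGCACACACATTT"
  # deletion of "CA" anywhere in the CA run shifts to position 4
  la <- left_align_indel(8L, "CA", "DEL", gs)
  expect_equal(la$pos, 4L)
  expect_equal(la$seq, "CA")
  # insertion of "CA" after the run left-aligns to before the run
  la <- left_align_indel(11L, "CA", "INS", gs)
  expect_equal(la$pos, 3L)
  # homopolymer deletion
  la <- left_align_indel(14L, "T", "DEL", gs)
  expect_equal(la$pos, 12L)
})
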