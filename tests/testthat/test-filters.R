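genome_f <- simulate_genome(5000, seed = 8)

alt_at <- function(g, pos) {
  setdiff(c("A", "C", "G", "T"), substr(g[[1]], pos, pos))[1]
}

# one fragment with an agreeing overlap mismatch of known combined quality
agreeing_pair <- function(q1, q2, start = 201L, fraglen = 130L,
                          qname = "f1", site = NULL) {
  site <- site %||% (start + fraglen - 75L)
  alt <- alt_at(genome_f, site)
  make_pair(genome_f, start = start, fraglen = fraglen, qname = qname,
            edits = list(list(mate = 1, gpos = site, alt = alt, q = q1),
                         list(mate = 2, gpos = site, alt = alt, q = q2)))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("combined base-quality threshold is inclusive at the boundary", {
  cfg <- filter_config(min_bq = 65, min_avg_bq = 0, only_overlap = TRUE,
                       strict_overlap = TRUE)
  # 32 + 32 = 64 < 65 -> rejected
  ext64 <- extract_mismatches(agreeing_pair(32, 32), cfg)
  expect_equal(nrow(ext64$sites), 0L)
  # 32 + 33 = 65 -> retained at exactly the threshold
  ext65 <- extract_mismatches(agreeing_pair(32, 33), cfg)
  expect_equal(nrow(ext65$sites), 1L)
  expect_equal(ext65$sites$bq, 65)
})

test_that("per-read base-quality minimum enforces both-mates support", {
  cfg <- filter_preset("D")
  expect_equal(nrow(extract_mismatches(agreeing_pair(32, 32), cfg)$sites), 1L)
  # summed quality 66 but one mate below 32 -> rejected
  expect_equal(nrow(extract_mismatches(agreeing_pair(31, 35), cfg)$sites), 0L)
})

test_that("fragment-level filters reject whole fragments with tallied reasons", {
  pair <- agreeing_pair(35, 35)
  # fragment length outside every window
  cfg <- filter_config(min_avg_bq = 0, fragment_windows = list(c(100, 120)))
  ext <- extract_mismatches(pair, cfg)
  expect_equal(nrow(ext$sites), 0L)
  expect_equal(ext$report$fragments_rejected[["fragment size"]], 1L)
  expect_equal(ext$report$filtered_bases, 0)
  # window covering 130 keeps it
  cfg2 <- filter_config(min_avg_bq = 0, min_bq = 65,
                        fragment_windows = list(c(100, 150)),
                        only_overlap = TRUE)
  expect_equal(nrow(extract_mismatches(pair, cfg2)$sites), 1L)
  # mapping quality
  low <- pair
  low$mapq <- c(10L, 60L)
  ext <- extract_mismatches(low, filter_config(min_mapq = 20, min_avg_bq = 0))
  expect_equal(nrow(ext$sites), 0L)
  expect_equal(ext$report$fragments_rejected[["mapping quality"]], 1L)
  # duplicates
  dup <- pair
  dup$duplicate <- TRUE
  ext <- extract_mismatches(dup, filter_config(min_avg_bq = 0))
  expect_equal(ext$report$fragments_rejected[["duplicate"]], 1L)
  expect_equal(nrow(ext$sites), 0L)
})

test_that("a read over the mismatch-count maximum invalidates its fragment", {
  site0 <- 255L
  edits <- lapply(0:15, function(k) {
    g <- site0 + 2L * k
    list(mate = 1, gpos = g, alt = alt_at(genome_f, g), q = 35)
  })
  pair <- make_pair(genome_f, start = 201L, fraglen = 250L, edits = edits)
  cfg <- filter_config(min_bq = 0, min_avg_bq = 0, max_mismatches = 15)
  ext <- extract_mismatches(pair, cfg)
  expect_equal(nrow(ext$sites), 0L)
  expect_equal(ext$report$fragments_rejected[["mismatch count"]], 1L)
  # 15 mismatches pass
  pair15 <- make_pair(genome_f, start = 201L, fraglen = 250L,
                      edits = edits[1:15])
  expect_equal(nrow(extract_mismatches(pair15, cfg)$sites), 15L)
})

test_that("whitelist and blacklist intervals gate mismatches by position", {
  pair <- agreeing_pair(35, 35)        # site at 256
  wl_in <- tibble::tibble(chrom = "chrS", start = 200L, end = 300L)
  wl_out <- tibble::tibble(chrom = "chrS", start = 400L, end = 500L)
  cfg <- function(...) filter_config(min_avg_bq = 0, min_bq = 65,
                                     only_overlap = TRUE, ...)
  expect_equal(nrow(extract_mismatches(pair, cfg(whitelist = wl_in))$sites), 1L)
  expect_equal(nrow(extract_mismatches(pair, cfg(whitelist = wl_out))$sites), 0L)
  expect_equal(nrow(extract_mismatches(pair, cfg(blacklist = wl_in))$sites), 0L)
  expect_equal(nrow(extract_mismatches(pair, cfg(blacklist = wl_out))$sites), 1L)
})

test_that("germline filtering is allele-specific, order-preserving and idempotent", {
  mm <- tibble::tibble(chrom = "chrS", pos = c(10L, 20L, 30L),
                       ref = c("A", "C", "G"), alt = c("T", "T", "A"),
                       class = "SBS", qname = c("f1", "f2", "f3"))
  # empty store: identity
  expect_identical(filter_germline(mm, germline_store()), mm)
  # one of three removed
  st <- germline_store(tibble::tibble(chrom = "chrS", pos = 20L, ref = "C",
                                      alt = "T"))
  out <- filter_germline(mm, st)
  expect_equal(out$pos, c(10L, 30L))
  # same position, different alt allele: retained
  st2 <- germline_store(tibble::tibble(chrom = "chrS", pos = 20L, ref = "C",
                                       alt = "G"))
  expect_equal(nrow(filter_germline(mm, st2)), 3L)
  # idempotence
  expect_identical(filter_germline(out, st), out)
})

test_that("germline stores translate anchored VCF indels to raw keys", {
  # deletion of T at 101 (VCF: pos 100 REF AT ALT A)
  st <- germline_store(tibble::tibble(chrom = "chrS", pos = 100L,
                                      ref = "AT", alt = "A"))
  mm <- tibble::tibble(chrom = "chrS", pos = 101L, ref = "T", alt = "",
                       class = "DEL", qname = "f1")
  expect_equal(nrow(filter_germline(mm, st)), 0L)
  # insertion of GG after 100 (VCF: pos 100 REF A ALT AGG)
  st2 <- germline_store(tibble::tibble(chrom = "chrS", pos = 100L,
                                       ref = "A", alt = "AGG"))
  mm2 <- tibble::tibble(chrom = "chrS", pos = 100L, ref = "", alt = "GG",
                        class = "INS", qname = "f1")
  expect_equal(nrow(filter_germline(mm2, st2)), 0L)
})

test_that("site aggregation counts distinct supporting fragments", {
  mm <- tibble::tibble(
    chrom = "chrS", pos = c(10L, 10L, 30L), ref = "C", alt = "T",
    class = "SBS", bq = c(70, 66, 70), qname = c("f1", "f2", "f3"))
  sites <- aggregate_support(mm)
  expect_equal(nrow(sites), 2L)
  expect_equal(sites$multi[sites$pos == 10L], 2L)
  expect_equal(sites$multi[sites$pos == 30L], 1L)
  # MULTI totals equal retained per-fragment mismatches
  expect_equal(sum(sites$multi), nrow(mm))
  # optional read-depth filter
  expect_equal(nrow(aggregate_support(mm, min_support = 2)), 1L)
  expect_equal(nrow(aggregate_support(mm[c(1, 3), ], min_support = 2)), 0L)
})

test_that("the filter stack is monotone: stricter configs retain subsets", {
  reads <- simulate_clean_reads(genome_f, depth = 20, seed = 12)
  key <- function(ext) paste(ext$mismatches$qname, ext$mismatches$pos,
                             ext$mismatches$alt)
  kA <- key(extract_mismatches(reads, filter_preset("A")))
  kB <- key(extract_mismatches(reads, filter_preset("B")))
  kC <- key(extract_mismatches(reads, filter_preset("C")))
  kD <- key(extract_mismatches(reads, filter_preset("D")))
  expect_true(all(kB %in% kA))
  expect_true(all(kC %in% kB))
  expect_true(all(kD %in% kC))
})
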