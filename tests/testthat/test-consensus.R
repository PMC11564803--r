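genome_c <- simulate_genome(2000, seed = 7)

test_that("agreeing overlap mismatches sum their base qualities", {
  # both mates read alt T at the same site with BQ 30 and 35
  pair <- make_pair(genome_c, start = 101L, fraglen = 130L,
                    edits = list(list(mate = 1, gpos = 151L, alt = "X",
                                      q = 30),
                                 list(mate = 2, gpos = 151L, alt = "X",
                                      q = 35)))
  # choose an alt different from the reference base at 151
  refb <- substr(genome_c[[1]], 151, 151)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  pair$seq <- vapply(seq_len(2), function(i) {
    s <- pair$seq[i]
    off <- 151L - pair$pos[i] + 1L
    substr(s, off, off) <- alt
    s
  }, character(1))
  pair$md <- vapply(seq_len(2), function(i) {
    compute_md(pair$seq[i], pair$cigar[i],
               substr(genome_c[[1]], pair$pos[i], pair$pos[i] + 99L))
  }, character(1))
  mm <- consensus_merge(pair)
  expect_equal(nrow(mm), 1L)
  expect_equal(mm$bq, 65)
  expect_equal(mm$bq_min, 30)
  expect_equal(mm$alt, alt)
  expect_true(mm$in_overlap)
})

test_that("disagreeing positions keep the higher-quality base at reduced quality", {
  refb <- substr(genome_c[[1]], 151, 151)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  # mate 1 carries the mismatch at Q40, mate 2 the reference base at Q20
  pair <- make_pair(genome_c, start = 101L, fraglen = 130L,
                    edits = list(list(mate = 1, gpos = 151L, alt = alt,
                                      q = 40),
                                 list(mate = 2, gpos = 151L, alt = refb,
                                      q = 20)))
  mm <- consensus_merge(pair)
  expect_equal(nrow(mm), 1L)
  expect_equal(mm$bq, 40 - 20 / 2)
  # mismatch loses against a higher-quality reference base
  pair2 <- make_pair(genome_c, start = 101L, fraglen = 130L,
                     edits = list(list(mate = 2, gpos = 151L, alt = alt,
                                       q = 20)))
  mm2 <- consensus_merge(pair2)
  expect_equal(nrow(mm2), 0L)
  # under strict consensus any disagreement is dropped
  mm3 <- consensus_merge(pair, only_overlap = TRUE, strict_overlap = TRUE)
  expect_equal(nrow(mm3), 0L)
})

test_that("equal-quality disagreements keep mate 1's base", {
  refb <- substr(genome_c[[1]], 151, 151)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  # mismatch on mate 1, equal qualities: mate 1's alt base wins
  p1 <- make_pair(genome_c, start = 101L, fraglen = 130L,
                  edits = list(list(mate = 1, gpos = 151L, alt = alt,
                                    q = 40)))
  mm1 <- consensus_merge(p1)
  expect_equal(nrow(mm1), 1L)
  expect_equal(mm1$bq, 40 - 20)
  # mismatch on mate 2, equal qualities: mate 1's reference base wins
  p2 <- make_pair(genome_c, start = 101L, fraglen = 130L,
                  edits = list(list(mate = 2, gpos = 151L, alt = alt,
                                    q = 40)))
  expect_equal(nrow(consensus_merge(p2)), 0L)
})

test_that("mismatches outside the overlap pass through, or drop under only-overlap", {
  refb <- substr(genome_c[[1]], 110, 110)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  pair <- make_pair(genome_c, start = 101L, fraglen = 130L,
                    edits = list(list(mate = 1, gpos = 110L, alt = alt,
                                      q = 38)))
  mm <- consensus_merge(pair)
  expect_equal(nrow(mm), 1L)
  expect_false(mm$in_overlap)
  expect_equal(mm$bq, 38)
  expect_equal(nrow(consensus_merge(pair, only_overlap = TRUE)), 0L)
  expect_equal(nrow(consensus_merge(pair, only_overlap = TRUE,
                                    strict_overlap = TRUE)), 0L)
})

test_that("consensus never invents mismatches absent from both mates", {
  set.seed(99)
  for (i in 1:50) {
    start <- 50L + sample.int(1500, 1)
    fraglen <- 110L + sample.int(80, 1)
    n_ed <- sample.int(4, 1)
    gpos_all <- start + sample.int(fraglen - 1L, n_ed)
    edits <- lapply(gpos_all, function(g) {
      refb <- substr(genome_c[[1]], g, g)
      list(mate = sample(1:2, 1), gpos = g,
           alt = sample(setdiff(c("A", "C", "G", "T"), refb), 1),
           q = sample(20:40, 1))
    })
    pair <- make_pair(genome_c, start = start, fraglen = fraglen,
                      edits = edits)
    mm <- consensus_merge(pair)
    expect_true(all(mm$gpos %in% gpos_all))
    # agreement conservation: combined quality of agreeing events equals the
    # exact sum of the inputs (all edits here carry known qualities)
    raw <- dplyr::bind_rows(lapply(edits, as.data.frame))
    for (j in seq_len(nrow(mm))) {
      here <- raw[raw$gpos == mm$gpos[j] & raw$alt == mm$alt[j], ]
      if (nrow(here) == 2L && mm$in_overlap[j]) {
        expect_equal(mm$bq[j], sum(here$q))
      }
    }
  }
})
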