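test_that("spike-in counts, downsampling and admixture fractions match the formulas", {
  # n_vars = r_m / 1e6 * n_genome
  expect_identical(spike_in_count(0.1, 3e9), 300L)
  expect_identical(spike_in_count(100, 3e9), 300000L)
  expect_identical(spike_in_count(0, 3e9), 0L)
  expect_identical(spike_in_count(10, 2e6), 20L)
  # f = n_genome * depth_t / (len_read * n_reads)
  expect_equal(downsample_fraction(3e9, 3, 100, 1.8e8), 0.5)
  expect_equal(downsample_fraction(2e6, 1, 100, 4e4), 0.5)
  # f_tumour = p_t / p_s; f_normal = (1 - f_tumour) * n_s / n_d
  fr <- admixture_fractions(0.12, 0.06, n_s = 1000, n_d = 1000)
  expect_equal(fr$f_tumour, 0.5)
  expect_equal(fr$f_normal, 0.5)
  fr2 <- admixture_fractions(0.2, 0.2, n_s = 500, n_d = 800)
  expect_equal(fr2$f_tumour, 1)
  expect_equal(fr2$f_normal, 0)
  expect_error(admixture_fractions(0.05, 0.1, 10, 10), "exceeds")
})

test_that("fixture genomes hit the target GC and contain every context", {
  fx <- make_fixture_genome(1e6, gc = 0.41, seed = 33)
  g <- fx$genome[[1]]
  gc <- sum(charToRaw(g) %in% charToRaw("GC")) / nchar(g)
  expect_lt(abs(gc - 0.41), 0.01)
  expect_length(plasmasig:::.context_index(g), 32L)
  expect_equal(fx$whitelist$start, 1001L)
  expect_equal(fx$whitelist$end, 999000L)
  # same seed, same genome
  expect_identical(fx$genome, make_fixture_genome(1e6, gc = 0.41,
                                                  seed = 33)$genome)
})

genome_s <- simulate_genome(2e5, seed = 44)

test_that("clean-read simulation honours the fragment model and error profile", {
  params <- read_sim_params()
  reads <- simulate_clean_reads(genome_s, depth = NA, params = params,
                                seed = 55, n_fragments = 10000)
  fl <- reads$fraglen[reads$mate == 1]
  expect_lt(abs(mean(fl) - 166), 1)
  expect_true(all(fl >= 100 & fl <= 500))
  expect_true(all(nchar(reads$seq) == 100))
  # error-free mode yields zero mismatches end to end
  clean <- simulate_clean_reads(genome_s, depth = 0.5, seed = 56,
                                error_scale = 0)
  expect_equal(nrow(extract_mismatches(clean, filter_preset("A"))$sites), 0L)
  # raw per-base mismatch rate matches the profile expectation within 5%
  noisy_profile <- tibble::tibble(q = c(20, 30), p = c(0.5, 0.5))
  pn <- read_sim_params(quality_profile = noisy_profile)
  nr <- simulate_clean_reads(genome_s, depth = NA, params = pn, seed = 57,
                             n_fragments = 20000)
  ext <- extract_mismatches(nr, filter_preset("A"))
  rate <- ext$report$mismatches_raw / ext$report$filtered_bases
  # doublet merging collapses a tiny fraction; compare raw event positions
  expected <- expected_error_rate(noisy_profile)
  expect_lt(abs(rate - expected) / expected, 0.05)
  # determinism
  r2 <- simulate_clean_reads(genome_s, depth = NA, params = pn, seed = 57,
                             n_fragments = 20000)
  expect_identical(nr, r2)
})

test_that("spike-in plans follow the signature's context distribution", {
  sigs <- synthetic_signature_catalogue("SBS96")
  plan <- plan_spike_in(sigs, r_m = 500, genome = genome_s, seed = 66,
                        signature_name = "SBS2")
  expect_equal(plan$n_vars, 100L)
  expect_equal(nrow(plan$variants), 100L)
  expect_false(anyDuplicated(plan$variants$pos) > 0)
  # every variant's pyrimidine-normalised context matches its channel
  g <- genome_s[[1]]
  ctx <- substring(g, plan$variants$pos - 1L, plan$variants$pos + 1L)
  lab <- classify_sbs(plan$variants$ref, plan$variants$alt, ctx)
  expect_identical(lab, plan$variants$channel)
  # channel distribution tracks the signature at large n (chi-squared)
  plan_big <- plan_spike_in(sigs, r_m = 25000, genome = genome_s, seed = 67,
                            signature_name = "SBS2")
  sig <- setNames(sigs$SBS2, sigs$channel)
  obs <- table(factor(plan_big$variants$channel, levels = names(sig)))
  keep <- sig * plan_big$n_vars >= 5
  chi <- suppressWarnings(chisq.test(obs[keep], p = sig[keep] / sum(sig[keep])))
  expect_gt(chi$p.value, 1e-4)
  # empty plan at r_m = 0
  expect_equal(nrow(plan_spike_in(sigs, r_m = 0, genome = genome_s,
                                  seed = 68,
                                  signature_name = "SBS2")$variants), 0L)
  # exhausted context pool errors with the channel name
  tiny <- simulate_genome(2000, seed = 69)
  expect_error(plan_spike_in(sigs, r_m = 3e5, genome = tiny, seed = 70,
                             signature_name = "SBS2"), "exhausted")
})

test_that("variant injection edits covering fragments at the allele frequency", {
  sigs <- synthetic_signature_catalogue("SBS96")
  reads <- simulate_clean_reads(genome_s, depth = 3, seed = 71,
                                error_scale = 0)
  plan <- plan_spike_in(sigs, r_m = 250, genome = genome_s, seed = 72,
                        allele_frequency = 1.0, signature_name = "SBS7a")
  inj <- inject_variants(reads, plan, genome_s, seed = 73)
  covered <- inj$truth[inj$truth$n_covering > 0, ]
  # AF 1: every covering fragment carries the variant
  expect_equal(covered$n_injected, covered$n_covering)
  # extraction recovers exactly the planned alleles (no errors simulated)
  ext <- extract_mismatches(inj$reads, filter_preset("A"))
  got <- unique(ext$mismatches[, c("pos", "ref", "alt")])
  expect_true(all(paste(got$pos, got$ref, got$alt) %in%
                  paste(plan$variants$pos, plan$variants$ref,
                        plan$variants$alt)))
  # binomial check at AF 0.1 over many covering fragments
  plan01 <- plan_spike_in(sigs, r_m = 2500, genome = genome_s, seed = 74,
                          allele_frequency = 0.1, signature_name = "SBS7a")
  inj01 <- inject_variants(reads, plan01, genome_s, seed = 75)
  n_cov <- sum(inj01$truth$n_covering)
  n_inj <- sum(inj01$truth$n_injected)
  expect_lt(abs(n_inj / n_cov - 0.1),
            3 * sqrt(0.1 * 0.9 / n_cov))
})

test_that("spiked signatures are conserved through extraction (catalogue cosine)", {
  sigs <- synthetic_signature_catalogue("SBS96")
  reads <- simulate_clean_reads(genome_s, depth = 3, seed = 81,
                                error_scale = 0)
  plan <- plan_spike_in(sigs, r_m = 2500, genome = genome_s, seed = 82,
                        allele_frequency = 0.5, signature_name = "SBS2")
  inj <- inject_variants(reads, plan, genome_s, seed = 83)
  ext <- extract_mismatches(inj$reads, filter_preset("default"),
                            genome = genome_s)
  cat96 <- build_catalogue(ext, genome_s, "SBS96")
  expect_gt(sum(cat96$count), 50)
  cs <- cosine_similarity(cat96$count / sum(cat96$count),
                          setNames(sigs$SBS2, sigs$channel)[cat96$channel])
  expect_gte(cs, 0.95)
})

test_that("downsampling keeps fragments jointly, reproducibly, at the right rate", {
  reads <- simulate_clean_reads(genome_s, depth = 2, seed = 91)
  expect_identical(downsample_reads(reads, f = 1, seed = 92), reads)
  d <- downsample_reads(reads, f = 0.5, seed = 92)
  # both mates kept or dropped together
  expect_true(all(table(d$qname) == 2L))
  n_frag <- length(unique(reads$qname))
  expect_lt(abs(length(unique(d$qname)) / n_frag - 0.5),
            3 * sqrt(0.25 / n_frag))
  expect_identical(d, downsample_reads(reads, f = 0.5, seed = 92))
  # target-depth interface and the unattainable case
  d2 <- downsample_reads(reads, depth_t = 1, n_genome = 2e5, seed = 93)
  expect_lt(abs(sum(nchar(d2$seq)) / 2e5 - 1), 0.1)
  expect_error(downsample_reads(reads, depth_t = 10, n_genome = 2e5,
                                seed = 94), "unattainable")
})

test_that("admixtures preserve read counts and tumour fractions in expectation", {
  src <- simulate_clean_reads(genome_s, depth = 1.5, seed = 95,
                              qname_prefix = "tum")
  don <- simulate_clean_reads(genome_s, depth = 1.5, seed = 96,
                              qname_prefix = "hlt")
  # p_t = p_s: output is the source
  mix1 <- admix_reads(src, don, p_s = 0.2, p_t = 0.2, seed = 97)
  expect_setequal(mix1$qname, src$qname)
  mix <- admix_reads(src, don, p_s = 0.2, p_t = 0.1, seed = 97)
  tum_frac <- mean(mix$tumour_derived)
  expect_lt(abs(tum_frac - 0.5), 0.05)
  expect_lt(abs(nrow(mix) / nrow(src) - 1), 0.1)
  # donor too small
  tiny_don <- don[1:20, ]
  expect_error(admix_reads(src, tiny_don, p_s = 0.2, p_t = 0.02, seed = 98),
               "donor too small")
})

test_that("error-rate measurement divides retained mismatches by filtered bases", {
  expect_equal(measure_error_rate(3, 3e7), 1e-7)
  expect_equal(measure_error_rate(0, 1e6), 0)
  expect_error(measure_error_rate(1, 0), "undefined")
})
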