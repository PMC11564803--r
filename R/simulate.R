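# Read-level simulator: error-only reads, signature-faithful spike-ins,
# depth downsampling and tumour-purity admixtures. Reads are emitted as
# already-aligned records with correct CIGAR/MD by construction, so the
# extraction stack can be exercised without an external aligner.

#' Sequencing quality profile
#'
#' A discrete per-base Phred quality distribution; substitution errors are
#' injected per base at rate `10^(-Q/10)` for the base's sampled quality.
#' The default mimics a modern Illumina run (mean error rate about 6.5e-4).
#'
#' @return Tibble with columns `q` (Phred) and `p` (probability).
#' @export
default_quality_profile <- function() {
  tibble(q = c(12, 22, 27, 32, 37, 41),
         p = c(0.004, 0.010, 0.050, 0.100, 0.335, 0.501))
}

#' @rdname default_quality_profile
#' @param profile A quality profile tibble.
#' @return `expected_error_rate()`: the profile's mean per-base substitution
#'   error rate.
#' @export
expected_error_rate <- function(profile = default_quality_profile()) {
  sum(profile$p * 10^(-profile$q / 10))
}

#' Read simulation parameters
#'
#' Fragment and error-model parameters of the cfDNA read simulator. Defaults
#' follow typical plasma cfDNA sequencing: 100 bp paired-end reads from
#' fragments with Normal(166, 24) lengths, truncated to
#' `[read_length, frag_max]`.
#'
#' @param read_length Read length in bp (default 100).
#' @param frag_mean,frag_sd Fragment length mean and SD in bp (defaults 166
#'   and 24).
#' @param frag_max Upper truncation for fragment lengths (default 500).
#' @param quality_profile Per-base quality distribution
#'   ([default_quality_profile()]).
#' @return A `plasmasig_sim_params` list.
#' @export
read_sim_params <- function(read_length = 100, frag_mean = 166, frag_sd = 24,
                            frag_max = 500,
                            quality_profile = default_quality_profile()) {
  stopifnot(frag_sd > 0, read_length >= 1, frag_max >= read_length,
            all(quality_profile$p >= 0), sum(quality_profile$p) > 0)
  structure(list(read_length = as.integer(read_length),
                 frag_mean = frag_mean, frag_sd = frag_sd,
                 frag_max = as.integer(frag_max),
                 quality_profile = quality_profile),
            class = "plasmasig_sim_params")
}

#' Simulate a random genome
#'
#' Generates a single-contig genome with a target GC fraction; base identity
#' is i.i.d., which guarantees all 32 pyrimidine-centred trinucleotide
#' contexts occur at any realistic length.
#'
#' @param length Contig length in bp.
#' @param gc GC fraction (default 0.41, genome-like).
#' @param seed Mandatory seed.
#' @param chrom Contig name.
#' @return Named character vector of length one (the genome representation
#'   used across the package).
#' @export
simulate_genome <- function(length, gc = 0.41, seed, chrom = "chrS") {
  stopifnot(length >= 1000)
  withr::with_seed(seed, {
    b <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  })
  setNames(paste(b, collapse = ""), chrom)
}

#' Simulate error-only aligned cfDNA reads
#'
#' Draws paired-end fragments with truncated-normal lengths and uniform
#' starts, emits both mates as aligned records (all-match CIGAR, MD recording
#' the injected substitution errors) and injects substitution errors per base
#' at rate `10^(-Q/10)` under the configured quality profile. Any deviation
#' of the output from the reference is therefore a sequencing error.
#'
#' @param genome Named character vector (single contig used).
#' @param depth Target haploid depth of coverage.
#' @param params [read_sim_params()].
#' @param seed Mandatory seed.
#' @param error_scale Multiplier on the per-base error probabilities (0
#'   disables errors entirely).
#' @param frag_mean,frag_sd Optional overrides of the fragment-length
#'   distribution (used for tumour-like vs healthy-like fragmentomics).
#' @param qname_prefix Fragment name prefix.
#' @param n_fragments Explicit fragment count (overrides `depth`).
#' @return Aligned-read tibble with columns `qname`, `chrom`, `pos`, `mate`,
#'   `cigar`, `md`, `seq`, `qual`, `mapq`, `fraglen`, `secondary`,
#'   `duplicate`, `proper`, coordinate-sorted.
#' @export
simulate_clean_reads <- function(genome, depth, params = read_sim_params(),
                                 seed, error_scale = 1,
                                 frag_mean = NULL, frag_sd = NULL,
                                 qname_prefix = "frag", n_fragments = NULL) {
  chrom <- names(genome)[1]
  gseq <- genome[[1]]
  L <- nchar(gseq)
  rl <- params$read_length
  fmean <- frag_mean %||% params$frag_mean
  fsd <- frag_sd %||% params$frag_sd
  if (L < params$frag_max) {
    abort("simulate_clean_reads(): reference shorter than the maximum fragment")
  }
  n <- n_fragments %||% max(1L, round(depth * L / (2 * rl)))
  prof <- params$quality_profile
  qs <- as.integer(prof$q)
  perr <- error_scale * 10^(-qs / 10)

  withr::with_seed(seed, {
    fl <- as.integer(pmin(pmax(round(rnorm(n, fmean, fsd)), rl),
                          min(params$frag_max, L)))
    start <- 1L + as.integer(floor(runif(n) * (L - fl + 1L)))
    pos1 <- start
    pos2 <- start + fl - rl
    pos <- c(rbind(pos1, pos2))        # interleaved mate1, mate2
    nreads <- 2L * n
    nb <- nreads * rl
    qidx <- sample.int(length(qs), nb, replace = TRUE, prob = prof$p)
    err <- runif(nb) < perr[qidx]
  })
  qv <- qs[qidx]
  seqs <- substring(gseq, pos, pos + rl - 1L)
  qual_all <- rawToChar(as.raw(qv + 33L))
  ends <- seq_len(nreads) * rl
  quals <- substring(qual_all, ends - rl + 1L, ends)

  md <- rep(as.character(rl), nreads)
  ei <- which(err)
  if (length(ei)) {
    ridx <- (ei - 1L) %/% rl + 1L
    off <- (ei - 1L) %% rl + 1L
    refb <- substr(seqs[ridx], off, off)
    withr::with_seed(seed + 1L, {
      shift <- sample.int(3L, length(ei), replace = TRUE)
    })
    bases <- c("A", "C", "G", "T")
    newb <- bases[((match(refb, bases) - 1L + shift) %% 4L) + 1L]
    keep <- !is.na(newb)               # skip N reference bases
    for (k in which(keep)) {
      substr(seqs[ridx[k]], off[k], off[k]) <- newb[k]
    }
    # MD tags for reads carrying errors
    byread <- split(seq_along(ei)[keep], ridx[keep])
    for (rn in names(byread)) {
      i <- as.integer(rn)
      js <- byread[[rn]]
      o <- off[js]
      ord <- order(o)
      o <- o[ord]
      rb <- refb[js][ord]
      gaps <- diff(c(0L, o)) - 1L
      md[i] <- paste0(paste0(gaps, rb, collapse = ""), rl - o[length(o)])
    }
  }

  tibble(
    qname = rep(paste0(qname_prefix, seq_len(n)), each = 2L),
    chrom = chrom,
    pos = pos,
    mate = rep(c(1L, 2L), n),
    cigar = paste0(rl, "M"),
    md = md,
    seq = seqs,
    qual = quals,
    mapq = 60L,
    fraglen = rep(fl, each = 2L),
    secondary = FALSE,
    duplicate = FALSE,
    proper = TRUE
  ) %>% arrange(.data$pos)
}

#' Number of variants to spike in for a target mutation rate
#'
#' `n_vars = round(r_m / 1e6 * n_genome)`: the count of somatic variants
#' matching a target mutation rate in mutations per megabase over a genome of
#' `n_genome` bases.
#'
#' @param r_m Target mutation rate (mutations per megabase).
#' @param n_genome Genome length in bp.
#' @return Integer variant count.
#' @examples
#' spike_in_count(0.1, 3e9) # 300
#' spike_in_count(100, 3e9) # 300000
#' @export
spike_in_count <- function(r_m, n_genome) {
  stopifnot(r_m >= 0, n_genome > 0)
  as.integer(round(r_m / 1e6 * n_genome))
}

# pyrimidine-normalised trinucleotide context of every genome position;
# returns a list: positions per context label (32 contexts)
.context_index <- function(gseq) {
  v <- as.integer(charToRaw(gseq))
  code <- rep(NA_integer_, 256)
  code[utf8ToInt("A") + 1L] <- 0L
  code[utf8ToInt("C") + 1L] <- 1L
  code[utf8ToInt("G") + 1L] <- 2L
  code[utf8ToInt("T") + 1L] <- 3L
  b <- code[v + 1L]
  L <- length(b)
  l <- b[1:(L - 2L)]
  c0 <- b[2:(L - 1L)]
  r <- b[3:L]
  pyr <- c0 == 1L | c0 == 3L
  # purine centre: reverse complement (complement code = 3 - code)
  key <- ifelse(pyr, 16L * l + 4L * c0 + r,
                16L * (3L - r) + 4L * (3L - c0) + (3L - l))
  key[is.na(l) | is.na(c0) | is.na(r)] <- NA_integer_
  posn <- 2:(L - 1L)
  ok <- !is.na(key)
  idx <- split(posn[ok], key[ok])
  bases <- c("A", "C", "G", "T")
  labs <- vapply(as.integer(names(idx)), function(k) {
    paste0(bases[k %/% 16L + 1L], bases[(k %/% 4L) %% 4L + 1L],
           bases[k %% 4L + 1L])
  }, character(1))
  setNames(idx, labs)
}

#' Plan a signature-faithful variant spike-in
#'
#' Chooses genome positions and alternate alleles whose pyrimidine-normalised
#' trinucleotide contexts follow a target SBS96 signature profile, at the
#' variant count implied by the target mutation rate. Positions whose central
#' base is a purine receive the reverse-complemented alternate allele, and no
#' position is used twice.
#'
#' @param signature Named numeric SBS96 profile (channel label -> probability)
#'   or a [signature_catalogue()] plus `signature_name`.
#' @param r_m Target mutation rate, mutations per megabase.
#' @param genome Named character vector (single contig used).
#' @param seed Mandatory seed.
#' @param allele_frequency Constant allele frequency applied at injection
#'   (default 0.1).
#' @param signature_name Column to take when `signature` is a catalogue.
#' @return A `plasmasig_spike_plan`: list with `variants` (tibble `chrom`,
#'   `pos`, `ref`, `alt`, `channel`, `context`), `n_vars`, `r_m`,
#'   `n_genome`, `allele_frequency`, `signature_name`.
#' @export
plan_spike_in <- function(signature, r_m, genome, seed,
                          allele_frequency = 0.1, signature_name = NULL) {
  if (inherits(signature, "plasmasig_signatures")) {
    stopifnot(!is.null(signature_name))
    sig <- setNames(signature[[signature_name]], signature$channel)
  } else {
    sig <- signature
    signature_name <- signature_name %||% "custom"
  }
  stopifnot(setequal(names(sig), sbs96_channels()))
  chrom <- names(genome)[1]
  gseq <- genome[[1]]
  n_genome <- nchar(gseq)
  n_vars <- spike_in_count(r_m, n_genome)
  empty <- tibble(chrom = character(0), pos = integer(0), ref = character(0),
                  alt = character(0), channel = character(0),
                  context = character(0))
  plan <- structure(list(variants = empty, n_vars = n_vars, r_m = r_m,
                         n_genome = n_genome,
                         allele_frequency = allele_frequency,
                         signature_name = signature_name, seed = seed),
                    class = "plasmasig_spike_plan")
  if (n_vars == 0L) return(plan)
  ctx_index <- .context_index(gseq)
  withr::with_seed(seed, {
    counts <- as.integer(rmultinom(1, n_vars, prob = sig))
    parts <- vector("list", length(sig))
    for (i in which(counts > 0L)) {
      channel <- names(sig)[i]
      ctx <- paste0(substr(channel, 1, 1), substr(channel, 3, 3),
                    substr(channel, 7, 7))
      alt_pyr <- substr(channel, 5, 5)
      pool <- ctx_index[[ctx]]
      if (is.null(pool) || length(pool) < counts[i]) {
        abort(sprintf(
          "plan_spike_in(): context pool for channel %s exhausted (%d needed, %d available)",
          channel, counts[i], length(pool %||% integer(0))))
      }
      pos <- sort(pool[sample.int(length(pool), counts[i])])
      refb <- substring(gseq, pos, pos)
      flipped <- refb %in% c("A", "G")
      alt <- ifelse(flipped, chartr("ACGT", "TGCA", alt_pyr), alt_pyr)
      parts[[i]] <- tibble(chrom = chrom, pos = pos, ref = refb, alt = alt,
                           channel = channel, context = ctx)
    }
  })
  plan$variants <- bind_rows(parts) %>% arrange(.data$pos)
  plan
}

#' @export
print.plasmasig_spike_plan <- function(x, ...) {
  cat(sprintf(
    "<spike-in plan: %s, r_m = %g/Mb over %g bp -> %d variants at AF %.2f>\n",
    x$signature_name, x$r_m, x$n_genome, x$n_vars, x$allele_frequency))
  invisible(x)
}

#' Inject planned variants into a simulated read set
#'
#' Every fragment overlapping a planned site carries the alternate allele
#' with probability equal to the plan's allele frequency; both mates are
#' edited when both cover the site, and MD tags are recomputed. Decisions are
#' per fragment and seed-reproducible. Sites covered by no fragment are
#' recorded as unrepresented in the truth table, not an error.
#'
#' @param reads Aligned-read tibble (all-match CIGARs, as produced by
#'   [simulate_clean_reads()]).
#' @param plan A [plan_spike_in()] result.
#' @param genome The reference the reads were simulated from.
#' @param seed Mandatory seed.
#' @return List with `reads` (edited tibble) and `truth` (tibble `chrom`,
#'   `pos`, `ref`, `alt`, `n_covering`, `n_injected`).
#' @export
inject_variants <- function(reads, plan, genome, seed) {
  vars <- plan$variants
  af <- plan$allele_frequency
  gseq <- genome[[1]]
  rlens <- nchar(reads$seq)
  starts <- reads$pos
  ord <- order(starts)
  sorted_starts <- starts[ord]
  maxlen <- max(rlens)
  edits_row <- integer(0); edits_off <- integer(0); edits_alt <- character(0)
  truth <- vars
  truth$n_covering <- 0L
  truth$n_injected <- 0L
  withr::local_seed(seed)
  for (i in seq_len(nrow(vars))) {
    s <- vars$pos[i]
    lo <- findInterval(s - maxlen, sorted_starts) + 1L
    hi <- findInterval(s, sorted_starts)
    if (hi < lo) next
    cand <- ord[lo:hi]
    cand <- cand[starts[cand] <= s & starts[cand] + rlens[cand] - 1L >= s]
    if (!length(cand)) next
    frags <- unique(reads$qname[cand])
    truth$n_covering[i] <- length(frags)
    pick <- frags[runif(length(frags)) < af]
    if (!length(pick)) next
    rows <- cand[reads$qname[cand] %in% pick]
    truth$n_injected[i] <- length(pick)
    edits_row <- c(edits_row, rows)
    edits_off <- c(edits_off, s - starts[rows] + 1L)
    edits_alt <- c(edits_alt, rep(vars$alt[i], length(rows)))
  }
  if (length(edits_row)) {
    for (k in seq_along(edits_row)) {
      substr(reads$seq[edits_row[k]], edits_off[k], edits_off[k]) <-
        edits_alt[k]
    }
    for (r in unique(edits_row)) {
      reads$md[r] <- compute_md(
        reads$seq[r], reads$cigar[r],
        substring(gseq, reads$pos[r], reads$pos[r] + rlens[r] - 1L))
    }
  }
  list(reads = reads, truth = truth)
}

#' Downsampling fraction for a target depth
#'
#' `f = (n_genome * depth_t) / (len_read * n_reads)`: the per-read keep
#' probability that reduces a read set to the target fold-coverage.
#'
#' @param n_genome Genome length (bp).
#' @param depth_t Target depth (fold-coverage).
#' @param len_read Read length (bp).
#' @param n_reads Total reads in the source set.
#' @return The subsampling fraction.
#' @export
downsample_fraction <- function(n_genome, depth_t, len_read, n_reads) {
  stopifnot(n_genome > 0, depth_t > 0, len_read > 0, n_reads > 0)
  n_genome * depth_t / (len_read * n_reads)
}

#' Downsample a read set to a target depth
#'
#' Keeps each fragment (both mates together) with probability `f`,
#' seed-reproducibly.
#'
#' @param reads Aligned-read tibble.
#' @param f Subsampling fraction in `(0, 1]`, or computed via `depth_t`.
#' @param depth_t Optional target depth; `f` is then derived with
#'   [downsample_fraction()] from the read set itself.
#' @param n_genome Genome length, required with `depth_t`.
#' @param seed Mandatory seed.
#' @return The reduced read tibble.
#' @export
downsample_reads <- function(reads, f = NULL, depth_t = NULL,
                             n_genome = NULL, seed) {
  if (is.null(f)) {
    stopifnot(!is.null(depth_t), !is.null(n_genome))
    f <- downsample_fraction(n_genome, depth_t,
                             len_read = round(mean(nchar(reads$seq))),
                             n_reads = nrow(reads))
  }
  if (f > 1) {
    abort(sprintf(
      "downsample_reads(): f = %.3f > 1; the target depth is unattainable from this read set",
      f))
  }
  if (f == 1) return(reads)
  frags <- unique(reads$qname)
  withr::with_seed(seed, {
    keep <- frags[runif(length(frags)) < f]
  })
  reads[reads$qname %in% keep, , drop = FALSE]
}

#' Tumour/donor read fractions for a purity admixture
#'
#' `f_tumour = p_t / p_s` is the fraction of source (tumour-bearing) reads
#' kept to dilute purity from `p_s` to `p_t`;
#' `f_normal = (1 - f_tumour) * n_s / n_d` is the fraction of healthy donor
#' reads sampled to restore the original read count.
#'
#' @param p_s,p_t Source and target tumour purity (`p_t <= p_s`).
#' @param n_s,n_d Source and donor read counts.
#' @return List with `f_tumour` and `f_normal`.
#' @export
admixture_fractions <- function(p_s, p_t, n_s, n_d) {
  if (p_t > p_s) abort("admixture_fractions(): target purity exceeds source")
  stopifnot(p_s > 0)
  f_tumour <- p_t / p_s
  f_normal <- (1 - f_tumour) * n_s / n_d
  list(f_tumour = f_tumour, f_normal = f_normal)
}

#' Mix source (tumour) and donor (healthy) reads at a target purity
#'
#' Keeps a Bernoulli(`f_tumour`) sample of source fragments and a
#' Bernoulli(`f_normal`) sample of donor fragments (renamed to avoid
#' fragment-name collisions), merges and coordinate-sorts. The expected read
#' count matches the source; the expected tumour-derived fraction is
#' `f_tumour`.
#'
#' @param source,donor Aligned-read tibbles.
#' @param p_s,p_t Source and target tumour purity.
#' @param seed Mandatory seed.
#' @return The mixed read tibble with a `tumour_derived` logical column.
#' @export
admix_reads <- function(source, donor, p_s, p_t, seed) {
  fr <- admixture_fractions(p_s, p_t, n_s = nrow(source), n_d = nrow(donor))
  if (fr$f_normal > 1) {
    abort(sprintf(
      "admix_reads(): donor too small (f_normal = %.3f > 1)", fr$f_normal))
  }
  sf <- unique(source$qname)
  df <- unique(donor$qname)
  withr::with_seed(seed, {
    keep_s <- sf[runif(length(sf)) < fr$f_tumour]
    keep_d <- df[runif(length(df)) < fr$f_normal]
  })
  s <- source[source$qname %in% keep_s, , drop = FALSE]
  d <- donor[donor$qname %in% keep_d, , drop = FALSE]
  d$qname <- paste0("donor_", d$qname)
  s$tumour_derived <- rep(TRUE, nrow(s))
  d$tumour_derived <- rep(FALSE, nrow(d))
  bind_rows(s, d) %>% arrange(.data$pos)
}

#' Post-filter error rate
#'
#' The retained-mismatch rate per filtered base: the number of retained
#' mismatches divided by the number of sequenced bases on fragments that
#' survived the same fragment-level filters.
#'
#' @param n_mismatches Retained mismatch count.
#' @param n_bases Filtered base count (same filter configuration).
#' @return Errors per base.
#' @export
measure_error_rate <- function(n_mismatches, n_bases) {
  if (n_bases <= 0) {
    abort("measure_error_rate(): zero filtered bases; the rate is undefined")
  }
  n_mismatches / n_bases
}
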