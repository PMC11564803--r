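# Workbench: end-to-end pipeline, fixture genome, and the scripted
# error-rate / limit-of-detection experiments.

# deterministic sub-seed derivation, kept inside 32-bit range
.subseed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483629)
}

#' Generate a fixture genome with a mappability whitelist
#'
#' A random contig at a genome-like GC fraction, plus a whitelist covering
#' the contig minus 1 kb margins. All 32 pyrimidine-centred trinucleotide
#' contexts are guaranteed present (checked).
#'
#' @param length Contig length (>= 1e5 recommended for context diversity).
#' @param gc GC fraction (default 0.41).
#' @param seed Mandatory seed.
#' @param margin Whitelist margin at each contig end (default 1000 bp).
#' @param chrom Contig name.
#' @return List with `genome` (named character vector) and `whitelist`
#'   (tibble `chrom`, `start`, `end`, 1-based closed).
#' @export
make_fixture_genome <- function(length = 2e6, gc = 0.41, seed,
                                margin = 1000, chrom = "chrS") {
  genome <- simulate_genome(length, gc = gc, seed = seed, chrom = chrom)
  idx <- .context_index(genome[[1]])
  if (length(idx) < 32L) {
    abort("make_fixture_genome(): not all trinucleotide contexts present; increase length")
  }
  list(
    genome = genome,
    whitelist = tibble(chrom = chrom, start = margin + 1L,
                       end = as.integer(length - margin))
  )
}

#' Sequencing error rates under nested filter presets
#'
#' Simulates error-only reads at the requested depth and measures the
#' retained-mismatch rate per filtered base under each stringency preset (see
#' [filter_preset()]). Because the presets are nested, the rates are monotone
#' non-increasing from A to D. Simulation and extraction run in fragment
#' chunks so arbitrarily large base counts fit in memory.
#'
#' @param genome Named character vector (single contig).
#' @param depth Simulated depth (ignored when `total_fragments` given).
#' @param params [read_sim_params()].
#' @param presets Preset names to evaluate.
#' @param seed Mandatory seed.
#' @param total_fragments Optional explicit fragment count (e.g. to reach a
#'   target number of sequenced bases).
#' @param chunk_fragments Fragments per chunk (default 50000).
#' @return Tibble `preset`, `mismatches`, `bases`, `rate`.
#' @export
error_rate_benchmark <- function(genome, depth = 3,
                                 params = read_sim_params(),
                                 presets = c("A", "B", "C", "D"), seed,
                                 total_fragments = NULL,
                                 chunk_fragments = 50000) {
  L <- nchar(genome[[1]])
  rl <- params$read_length
  n_total <- total_fragments %||% max(1L, round(depth * L / (2 * rl)))
  configs <- lapply(presets, filter_preset)
  names(configs) <- presets
  mism <- setNames(numeric(length(presets)), presets)
  bases <- setNames(numeric(length(presets)), presets)
  remaining <- n_total
  chunk_i <- 0L
  while (remaining > 0L) {
    chunk_i <- chunk_i + 1L
    n_i <- min(chunk_fragments, remaining)
    remaining <- remaining - n_i
    reads <- simulate_clean_reads(genome, depth = NA, params = params,
                                  seed = .subseed(seed, chunk_i),
                                  n_fragments = n_i)
    for (p in presets) {
      ext <- extract_mismatches(reads, config = configs[[p]])
      mism[p] <- mism[p] + nrow(ext$mismatches)
      bases[p] <- bases[p] + ext$report$filtered_bases
    }
  }
  tibble(preset = presets, mismatches = as.numeric(mism),
         bases = as.numeric(bases),
         rate = as.numeric(mism) / as.numeric(bases))
}

#' Run the full inference pipeline on an aligned read set
#'
#' Chains extraction, catalogue construction, signature refitting and
#' (optionally) panel-threshold detection calls; when `out_dir` is given,
#' every stage's outputs land there (VCF, catalogue/weights/calls TSVs and a
#' JSON run report including the configuration hash).
#'
#' @param reads Aligned-read tibble.
#' @param genome Named character vector of chromosome sequences.
#' @param signatures A [signature_catalogue()].
#' @param config A [filter_config()]/[filter_preset()].
#' @param germline Optional [germline_store()].
#' @param thresholds Optional `plasmasig_thresholds` for detection calls.
#' @param sample Sample name.
#' @param out_dir Optional output directory.
#' @param count_by Catalogue counting mode (see [build_catalogue()]).
#' @return A `plasmasig_run` list: `extract`, `catalogue`, `fit`, `calls`
#'   (NULL without thresholds) and `report`.
#' @export
run_pipeline <- function(reads, genome, signatures,
                         config = filter_preset("default"),
                         germline = NULL, thresholds = NULL,
                         sample = "sample", out_dir = NULL,
                         count_by = "site") {
  scheme <- attr(signatures, "scheme")
  ext <- extract_mismatches(reads, config = config, germline = germline,
                            genome = genome, sample = sample)
  cat <- build_catalogue(ext, genome, scheme = scheme, sample = sample,
                         count_by = count_by)
  fit <- fit_signature_weights(cat, signatures)
  calls <- NULL
  if (!is.null(thresholds)) {
    calls <- call_detected(tidy(fit), thresholds)
  }
  report <- c(ext$report, list(
    scheme = scheme,
    catalogue_total = sum(cat$count),
    catalogue_excluded = attr(cat, "n_excluded"),
    fit = as.list(glance(fit)),
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("plasmasig"))
  ))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vcf(ext$sites, file.path(out_dir, paste0(sample, ".vcf")),
              sample = sample, genome = genome)
    write_catalogue(cat, file.path(out_dir, paste0(sample, ".catalogue.tsv")))
    utils::write.table(tidy(fit),
                       file.path(out_dir, paste0(sample, ".weights.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(calls)) {
      utils::write.table(calls,
                         file.path(out_dir, paste0(sample, ".calls.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report,
                         file.path(out_dir, paste0(sample, ".report.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(extract = ext, catalogue = cat, fit = fit, calls = calls,
                 report = report),
            class = "plasmasig_run")
}

#' @export
print.plasmasig_run <- function(x, ...) {
  print(x$extract)
  print(x$fit)
  if (!is.null(x$calls)) {
    det <- x$calls$signature[x$calls$detected]
    cat(sprintf("  detected: %s\n",
                if (length(det)) paste(det, collapse = ", ") else "none"))
  }
  invisible(x)
}

# simulate one tumour-like source and one healthy donor read set, with
# signature spike-ins; shared building block of the titration experiments
.sim_admixture_inputs <- function(genome, signatures, target, r_m,
                                  allele_frequency, background, depth,
                                  params, params_donor = NULL, seed) {
  src <- simulate_clean_reads(genome, depth, params,
                              seed = .subseed(seed, 1), qname_prefix = "tum")
  plan <- plan_spike_in(signatures, r_m = r_m, genome = genome,
                        seed = .subseed(seed, 2),
                        allele_frequency = allele_frequency,
                        signature_name = target)
  src <- inject_variants(src, plan, genome, seed = .subseed(seed, 3))$reads
  donor <- simulate_clean_reads(genome, depth, params_donor %||% params,
                                seed = .subseed(seed, 4),
                                qname_prefix = "hlt")
  if (!is.null(background)) {
    bplan <- plan_spike_in(signatures, r_m = background$r_m, genome = genome,
                           seed = .subseed(seed, 5),
                           allele_frequency = background$allele_frequency,
                           signature_name = background$signature)
    donor <- inject_variants(donor, bplan, genome,
                             seed = .subseed(seed, 6))$reads
  }
  list(source = src, donor = donor, plan = plan)
}

#' Limit-of-detection titration over tumour purity and sequencing depth
#'
#' Reproduces the in-silico admixture experiments at desk scale: a
#' tumour-like source (target signature spiked at constant allele frequency)
#' is diluted with healthy donor reads (carrying a low-level flat background
#' signature, as healthy plasma does) to a grid of target purities, and
#' separately downsampled to a grid of depths at fixed purity. Each replicate
#' runs the full extraction/fit/call pipeline; seeds are held stable across
#' titration levels so selections are nested, mirroring fixed-seed
#' downsampling practice.
#'
#' @param genome Named character vector (single contig).
#' @param signatures A [signature_catalogue()] containing `target` and the
#'   background signature.
#' @param thresholds `plasmasig_thresholds` with a threshold for `target`.
#' @param target Target signature name (e.g. `"SBS2"`, `"SBS7a"`).
#' @param purities Purity grid (tumour fraction of cfDNA) at `fixed_depth`.
#' @param depths Depth grid at `fixed_purity`.
#' @param fixed_depth Depth for the purity titration (default 3).
#' @param fixed_purity Purity for the depth titration (default the maximum of
#'   `purities`).
#' @param source_purity Notional purity of the undiluted source (default
#'   0.2); `f_tumour = p_t / source_purity`.
#' @param r_m Spiked mutation rate in the source, mutations/Mb (default 600 —
#'   on a megabase-scale fixture this matches the absolute variant count of a
#'   modest genome-wide burden, e.g. 0.2/Mb over a 3 Gb genome).
#' @param allele_frequency Spike allele frequency (default 0.1).
#' @param background Donor background spike: list with `signature`, `r_m`,
#'   `allele_frequency`.
#' @param replicates In-silico replicates per grid point (default 20).
#' @param config Extraction filter configuration.
#' @param params [read_sim_params()].
#' @param seed Mandatory seed.
#' @return Tibble `axis`, `replicate`, `purity`, `depth`, `total_mutations`,
#'   `weight`, `threshold`, `detected`.
#' @export
detection_titration <- function(genome, signatures, thresholds,
                                target = "SBS7a",
                                purities = c(0.01, 0.05, 0.10),
                                depths = c(0.5, 1, 3),
                                fixed_depth = 3,
                                fixed_purity = max(purities),
                                source_purity = 0.2,
                                r_m = 600, allele_frequency = 0.1,
                                background = list(signature = "SBS5",
                                                  r_m = 100,
                                                  allele_frequency = 0.5),
                                replicates = 20,
                                config = filter_preset("default"),
                                params = read_sim_params(), seed) {
  L <- nchar(genome[[1]])
  thr_tab <- tidy(thresholds)
  thr <- thr_tab$threshold[thr_tab$signature == target]
  out <- vector("list", replicates)
  for (rep_i in seq_len(replicates)) {
    rs <- .subseed(seed, 1000 + rep_i)
    inp <- .sim_admixture_inputs(genome, signatures, target, r_m,
                                 allele_frequency, background,
                                 depth = max(c(depths, fixed_depth)),
                                 params = params, seed = rs)
    one <- function(p_t, depth_t, axis) {
      mixed <- admix_reads(inp$source, inp$donor, p_s = source_purity,
                           p_t = p_t, seed = .subseed(rs, 7))
      if (depth_t < max(c(depths, fixed_depth))) {
        mixed <- downsample_reads(mixed, depth_t = depth_t, n_genome = L,
                                  seed = .subseed(rs, 8))
      }
      ext <- extract_mismatches(mixed, config = config, genome = genome)
      cat <- build_catalogue(ext, genome, "SBS96")
      fit <- fit_signature_weights(cat, signatures)
      w <- fit$weights$weight[fit$weights$signature == target]
      tibble(axis = axis, replicate = rep_i, purity = p_t, depth = depth_t,
             total_mutations = sum(cat$count), weight = w,
             threshold = thr, detected = w > thr)
    }
    res <- bind_rows(
      purrr::map_dfr(purities, one, depth_t = fixed_depth, axis = "purity"),
      purrr::map_dfr(depths, function(d) one(fixed_purity, d, "depth"))
    )
    out[[rep_i]] <- res
  }
  bind_rows(out)
}

#' Effect of the fragment-size filter on the fitted tumour signature
#'
#' Builds an admixture in which tumour-derived fragments are shorter
#' (Normal(145, 22)) than healthy donor fragments (Normal(166, 24)), then
#' fits the target signature weight with and without a fragment-size window
#' that favours the short fragments — the cfDNA fragmentomics enrichment
#' experiment.
#'
#' @inheritParams detection_titration
#' @param purity Target purity of the admixture (default 0.1).
#' @param window Fragment-length window applied in the filtered arm (default
#'   `c(90, 150)`).
#' @param tumour_frag,donor_frag `c(mean, sd)` fragment-length parameters.
#' @param replicates Number of replicate admixtures.
#' @return Tibble `replicate`, `size_filtered`, `weight`, `total_mutations`.
#' @export
fragmentomics_experiment <- function(genome, signatures, target = "SBS7a",
                                     purity = 0.1, source_purity = 0.2,
                                     r_m = 600, allele_frequency = 0.1,
                                     background = list(signature = "SBS5",
                                                       r_m = 100,
                                                       allele_frequency = 0.5),
                                     window = c(90, 150),
                                     tumour_frag = c(145, 22),
                                     donor_frag = c(166, 24),
                                     depth = 3, replicates = 5,
                                     config = filter_preset("default"),
                                     params = read_sim_params(), seed) {
  out <- vector("list", replicates)
  for (rep_i in seq_len(replicates)) {
    rs <- .subseed(seed, 2000 + rep_i)
    p_t <- read_sim_params(read_length = params$read_length,
                           frag_mean = tumour_frag[1], frag_sd = tumour_frag[2],
                           frag_max = params$frag_max,
                           quality_profile = params$quality_profile)
    p_d <- read_sim_params(read_length = params$read_length,
                           frag_mean = donor_frag[1], frag_sd = donor_frag[2],
                           frag_max = params$frag_max,
                           quality_profile = params$quality_profile)
    inp <- .sim_admixture_inputs(genome, signatures, target, r_m,
                                 allele_frequency, background, depth,
                                 params = p_t, params_donor = p_d, seed = rs)
    mixed <- admix_reads(inp$source, inp$donor, p_s = source_purity,
                         p_t = purity, seed = .subseed(rs, 7))
    cfg_win <- config
    cfg_win$fragment_windows <- list(window)
    res <- purrr::map_dfr(list(`FALSE` = config, `TRUE` = cfg_win),
                          function(cfg) {
      ext <- extract_mismatches(mixed, config = cfg, genome = genome)
      cat <- build_catalogue(ext, genome, "SBS96")
      fit <- fit_signature_weights(cat, signatures)
      tibble(weight = fit$weights$weight[fit$weights$signature == target],
             total_mutations = sum(cat$count))
    }, .id = "size_filtered")
    res$size_filtered <- as.logical(res$size_filtered)
    res$replicate <- rep_i
    out[[rep_i]] <- res[, c("replicate", "size_filtered", "weight",
                            "total_mutations")]
  }
  bind_rows(out)
}
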