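#' Filter configuration for mismatch extraction
#'
#' Collects every tunable threshold of the extraction filter stack. All
#' quality thresholds are inclusive (a mismatch passes at exactly the
#' threshold value). The combined base-quality threshold `min_bq` applies to
#' the consensus quality (the sum of both mates' base qualities where mates
#' agree inside their overlap); outside overlaps the raw single-read quality
#' is compared against the same threshold. `min_read_bq` is an additional
#' per-read minimum on the qualities supporting a retained base, used to
#' express "both mates >= 32"-style regimes.
#'
#' @param min_mapq Minimum mapping quality per read (default 20).
#' @param min_bq Minimum combined base quality per mismatch (default 65).
#' @param min_avg_bq Minimum mean base quality across each read (default 25).
#' @param min_mismatches,max_mismatches Bounds on the number of raw mismatch
#'   events per read (defaults 1 and 15). A read exceeding the maximum
#'   invalidates its whole fragment.
#' @param fragment_windows Optional list of `c(min, max)` fragment-length
#'   windows (bp); fragments outside every window are rejected. Used as the
#'   cfDNA fragmentomics size filter.
#' @param consensus Apply read-pair overlap consensus at all (default TRUE;
#'   disabled only by the "no filters" preset, which retains raw mismatches).
#' @param only_overlap Keep only mismatches inside the mate overlap.
#' @param strict_overlap With `only_overlap`, additionally require both mates
#'   to agree on the mismatch.
#' @param min_read_bq Per-read base-quality minimum (default 0).
#' @param whitelist,blacklist Optional interval tibbles (`chrom`, `start`,
#'   `end`; 1-based closed, as returned by [read_bed()]). Mismatches must fall
#'   inside the whitelist and outside the blacklist.
#' @param min_support Minimum number of distinct supporting fragments per
#'   site (optional read-depth filter; default 1).
#' @return A `plasmasig_filter_config` list.
#' @export
filter_config <- function(min_mapq = 20, min_bq = 65, min_avg_bq = 25,
                          min_mismatches = 1, max_mismatches = 15,
                          fragment_windows = NULL, consensus = TRUE,
                          only_overlap = FALSE, strict_overlap = FALSE,
                          min_read_bq = 0,
                          whitelist = NULL, blacklist = NULL,
                          min_support = 1) {
  if (any(c(min_mapq, min_bq, min_avg_bq, min_read_bq) < 0)) {
    abort("filter_config(): quality thresholds must be >= 0")
  }
  if (min_mismatches > max_mismatches) {
    abort("filter_config(): min_mismatches > max_mismatches")
  }
  if (!is.null(fragment_windows)) {
    if (!is.list(fragment_windows)) fragment_windows <- list(fragment_windows)
    for (w in fragment_windows) {
      if (length(w) != 2L || w[1] > w[2]) {
        abort("filter_config(): each fragment window must be c(min, max) with min <= max")
      }
    }
  }
  for (iv in list(whitelist, blacklist)) {
    if (!is.null(iv) && (!is.data.frame(iv) ||
        !all(c("chrom", "start", "end") %in% names(iv)) ||
        any(iv$start > iv$end))) {
      abort("filter_config(): interval lists need chrom/start/end with start <= end")
    }
  }
  structure(
    list(
      min_mapq = min_mapq, min_bq = min_bq, min_avg_bq = min_avg_bq,
      min_mismatches = min_mismatches, max_mismatches = max_mismatches,
      fragment_windows = fragment_windows,
      consensus = isTRUE(consensus),
      only_overlap = isTRUE(only_overlap),
      strict_overlap = isTRUE(strict_overlap),
      min_read_bq = min_read_bq,
      whitelist = whitelist, blacklist = blacklist,
      min_support = min_support
    ),
    class = "plasmasig_filter_config"
  )
}

#' Named stringency presets for the extraction filter stack
#'
#' Four nested presets of increasing stringency, plus the package default:
#' \describe{
#'   \item{A}{no filters: every raw mismatch is retained.}
#'   \item{B}{read-pair consensus: only mismatches inside mate overlaps,
#'     after consensus resolution of disagreeing bases.}
#'   \item{C}{strict consensus: both mates must report the same base.}
#'   \item{D}{strict consensus with per-read base quality >= 32.}
#'   \item{default}{the full stack: MQ >= 20, combined BQ >= 65, mean read
#'     BQ >= 25, 1-15 mismatches per read, strict overlap consensus.}
#' }
#' Presets A-D deliberately disable the quality/mismatch-count filters so
#' that each step isolates the effect of the overlap-consensus rules; the
#' retained set of each preset is a superset of the next.
#'
#' @param name One of `"A"`, `"B"`, `"C"`, `"D"`, `"default"`.
#' @param ... Overrides passed on to [filter_config()].
#' @return A `plasmasig_filter_config`.
#' @export
filter_preset <- function(name = c("default", "A", "B", "C", "D"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    A = list(min_mapq = 0, min_bq = 0, min_avg_bq = 0, min_mismatches = 0,
             max_mismatches = Inf, consensus = FALSE),
    B = list(min_mapq = 0, min_bq = 0, min_avg_bq = 0, min_mismatches = 0,
             max_mismatches = Inf, only_overlap = TRUE),
    C = list(min_mapq = 0, min_bq = 0, min_avg_bq = 0, min_mismatches = 0,
             max_mismatches = Inf, only_overlap = TRUE, strict_overlap = TRUE),
    D = list(min_mapq = 0, min_bq = 0, min_avg_bq = 0, min_mismatches = 0,
             max_mismatches = Inf, only_overlap = TRUE, strict_overlap = TRUE,
             min_read_bq = 32),
    default = list(only_overlap = TRUE, strict_overlap = TRUE)
  )
  over <- list(...)
  do.call(filter_config, utils::modifyList(base, over))
}

#' Read a BED file into a 1-based closed interval tibble
#'
#' BED intervals are 0-based half-open; all user-facing coordinates in this
#' package are 1-based closed, so `start` is shifted by one.
#'
#' @param path Path to a plain-text BED file (first three columns used).
#' @return A tibble with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  tibble(chrom = as.character(bed[[1]]),
         start = as.integer(bed[[2]]) + 1L,
         end = as.integer(bed[[3]]))
}

.in_intervals <- function(chrom, pos, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    return(rep(FALSE, length(pos)))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(intervals$chrom,
                              IRanges::IRanges(intervals$start, intervals$end))
  IRanges::overlapsAny(q, s)
}

#' Germline variant stores
#'
#' A germline store is an allele-specific lookup used to remove known
#' germline variants from the candidate mismatch set. Keys are
#' `(chromosome, position, ref, alt)` in the package's raw event
#' representation (deletions keyed at the first deleted base with an empty
#' alt; insertions keyed at the base 5' of the insertion with an empty ref),
#' with alleles as written on the reference forward strand.
#'
#' `germline_store()` builds a store from a tibble of VCF-style records
#' (`chrom`, `pos`, `ref`, `alt`); `read_germline_store()` reads either a
#' 4-column tab-separated file (chrom, pos, ref, alt; no header) or a VCF.
#'
#' @param variants Tibble with columns `chrom`, `pos`, `ref`, `alt`
#'   (VCF-style anchored alleles).
#' @param description Free-text provenance label.
#' @return A `plasmasig_germline_store`.
#' @export
germline_store <- function(variants = NULL, description = "user") {
  keys <- character(0)
  if (!is.null(variants) && nrow(variants) > 0L) {
    ref <- toupper(variants$ref)
    alt <- toupper(variants$alt)
    pos <- as.integer(variants$pos)
    chrom <- as.character(variants$chrom)
    # convert VCF anchored representation to raw events
    n <- length(ref)
    kp <- character(n)
    for (i in seq_len(n)) {
      r <- ref[i]; a <- alt[i]
      if (nchar(r) == nchar(a)) {
        kp[i] <- paste(chrom[i], pos[i], r, a, sep = ":")
      } else if (nchar(r) > nchar(a) && startsWith(r, a)) {
        kp[i] <- paste(chrom[i], pos[i] + nchar(a),
                       substr(r, nchar(a) + 1L, nchar(r)), "", sep = ":")
      } else if (nchar(a) > nchar(r) && startsWith(a, r)) {
        kp[i] <- paste(chrom[i], pos[i] + nchar(r) - 1L, "",
                       substr(a, nchar(r) + 1L, nchar(a)), sep = ":")
      } else {
        kp[i] <- paste(chrom[i], pos[i], r, a, sep = ":")
      }
    }
    keys <- unique(kp)
  }
  env <- new.env(parent = emptyenv(), size = max(1L, length(keys)))
  for (k in keys) assign(k, TRUE, envir = env)
  structure(list(env = env, n = length(keys), description = description),
            class = "plasmasig_germline_store")
}

#' @rdname germline_store
#' @param path Path to a 4-column TSV or a VCF file.
#' @export
read_germline_store <- function(path) {
  first <- tryCatch(suppressWarnings(readLines(path, n = 200L)),
                    error = function(e) {
    abort(sprintf("cannot read germline store '%s': %s", path,
                  conditionMessage(e)))
  })
  if (any(startsWith(first, "##fileformat=VCF"))) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      abort("reading VCF germline stores requires the vcfR package")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    recs <- tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                   ref = fix$REF, alt = fix$ALT) %>%
      tidyr::separate_rows("alt", sep = ",")
    return(germline_store(recs, description = path))
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer",
                                          "character", "character"))
  germline_store(tibble(chrom = tab[[1]], pos = tab[[2]],
                        ref = tab[[3]], alt = tab[[4]]),
                 description = path)
}

#' @export
print.plasmasig_germline_store <- function(x, ...) {
  cat(sprintf("<germline store: %d variants (%s)>\n", x$n, x$description))
  invisible(x)
}

#' Remove known germline variants from a mismatch set
#'
#' Removes exactly those mismatches whose `(chrom, pos, ref, alt)` key is
#' present in the store; lookup is allele-specific and order is preserved.
#' Indels should be left-aligned before lookup (extraction does this when a
#' reference is supplied).
#'
#' @param mismatches Tibble with columns `chrom`, `pos` (raw event
#'   representation), `ref`, `alt`.
#' @param store A [germline_store()].
#' @return The retained mismatches.
#' @export
filter_germline <- function(mismatches, store) {
  if (is.null(store) || nrow(mismatches) == 0L || store$n == 0L) {
    return(mismatches)
  }
  keys <- paste(mismatches$chrom, mismatches$pos,
                toupper(mismatches$ref), toupper(mismatches$alt), sep = ":")
  hit <- vapply(keys, function(k) exists(k, envir = store$env,
                                         inherits = FALSE), logical(1))
  mismatches[!hit, , drop = FALSE]
}

#' Fragment-level filter decisions
#'
#' Evaluates the whole-fragment filters (duplicate/secondary flags, mapping
#' quality, mean base quality, fragment-length windows) for every fragment in
#' an aligned read set, tallying one rejection reason per fragment. The
#' per-read mismatch-count bounds are evaluated later, once mismatches have
#' been reconstructed.
#'
#' @param reads Aligned read tibble (see [simulate_clean_reads()] for the
#'   schema).
#' @param config A [filter_config()].
#' @return A tibble with one row per fragment: `qname`, `keep`, `reason`
#'   (`NA` when kept).
#' @export
apply_fragment_filters <- function(reads, config = filter_config()) {
  uq <- unique(reads$qname)
  n <- length(uq)
  gid <- match(reads$qname, uq)
  # grouped min via sort-and-first (fragments have at most two mates, but
  # this is correct for any group size)
  gmin <- function(x) {
    o <- order(gid, x)
    x[o][!duplicated(gid[o])]
  }
  gmax <- function(x) {
    o <- order(gid, -x)
    x[o][!duplicated(gid[o])]
  }
  dup <- as.numeric(rowsum(as.integer(reads$duplicate), gid)) > 0
  allsec <- as.numeric(rowsum(as.integer(!reads$secondary), gid)) == 0
  min_mapq <- gmin(reads$mapq)
  min_mean_q <- gmin(phred_means(reads$qual))
  fraglen <- gmax(abs(reads$fraglen))
  reason <- rep(NA_character_, n)
  reason[min_mean_q < config$min_avg_bq] <- "mean base quality"
  reason[min_mapq < config$min_mapq] <- "mapping quality"
  if (!is.null(config$fragment_windows)) {
    inwin <- rep(FALSE, n)
    for (w in config$fragment_windows) {
      inwin <- inwin | (fraglen >= w[1] & fraglen <= w[2])
    }
    reason[!inwin] <- "fragment size"
  }
  reason[allsec] <- "secondary alignment"
  reason[dup] <- "duplicate"
  tibble(qname = uq, keep = is.na(reason), reason = reason)
}

#' Mean Phred quality per read
#'
#' @param quals Character vector of Phred+33 quality strings.
#' @return Numeric vector of mean per-base qualities.
#' @export
phred_means <- function(quals) {
  n <- length(quals)
  if (n == 0L) return(numeric(0))
  lens <- nchar(quals)
  all <- utf8ToInt(paste(quals, collapse = "")) - 33L
  ends <- cumsum(lens)
  cs <- c(0, cumsum(as.numeric(all)))
  sums <- cs[ends + 1L] - cs[ends - lens + 1L]
  out <- sums / lens
  out[lens == 0L] <- NA_real_
  out
}
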