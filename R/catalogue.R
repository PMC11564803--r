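# Mutation catalogues: channel-count vectors over a classification scheme.

.new_catalogue <- function(counts, scheme, sample, n_excluded = 0L) {
  channels <- switch(scheme, SBS96 = sbs96_channels(),
                     DBS78 = dbs78_channels(), ID83 = id83_channels(),
                     abort("unknown scheme"))
  full <- setNames(rep(0, length(channels)), channels)
  counts <- counts[names(counts) %in% channels]
  full[names(counts)] <- counts
  structure(tibble(channel = channels, count = as.numeric(full)),
            scheme = scheme, sample = sample, n_excluded = n_excluded,
            class = c("plasmasig_catalogue", class(tibble())))
}

#' Build mutation catalogues from extracted site records
#'
#' Classifies every retained mismatch into its COSMIC channel — SBS96 via the
#' pyrimidine-normalised trinucleotide context, DBS78 via canonical doublet
#' orientation, ID83 via repeat/microhomology context — and counts events per
#' channel. Events whose context contains `N` (or whose flanks run off the
#' contig) are tallied as excluded rather than classified.
#'
#' @param sites Site tibble from [extract_mismatches()] (or
#'   [read_vcf_sites()]), or a `plasmasig_extract` object.
#' @param genome Named character vector of chromosome sequences.
#' @param scheme `"SBS96"`, `"DBS78"` or `"ID83"`.
#' @param sample Sample name stored on the catalogue.
#' @param count_by `"site"` (default: each site counts once) or
#'   `"fragment"` (each site counts `multi` times).
#' @return A `plasmasig_catalogue`: a tibble (`channel`, `count`) in canonical
#'   channel order with attributes `scheme`, `sample` and `n_excluded`.
#' @export
build_catalogue <- function(sites, genome, scheme = c("SBS96", "DBS78",
                                                      "ID83"),
                            sample = "sample",
                            count_by = c("site", "fragment")) {
  scheme <- match.arg(scheme)
  count_by <- match.arg(count_by)
  if (inherits(sites, "plasmasig_extract")) sites <- sites$sites
  want_class <- switch(scheme, SBS96 = "SBS", DBS78 = "DBS",
                       ID83 = c("INS", "DEL"))
  s <- sites[sites$class %in% want_class, , drop = FALSE]
  if (nrow(s) == 0L) return(.new_catalogue(numeric(0), scheme, sample))
  w <- if (count_by == "fragment") s$multi else rep(1, nrow(s))

  if (scheme == "SBS96") {
    ctx <- character(nrow(s))
    for (ch in unique(s$chrom)) {
      i <- s$chrom == ch
      cs <- genome[[ch]]
      ctx[i] <- substring(cs, s$pos[i] - 1L, s$pos[i] + 1L)
    }
    ok <- nchar(ctx) == 3L
    lab <- rep(NA_character_, nrow(s))
    lab[ok] <- classify_sbs(s$ref[ok], s$alt[ok], ctx[ok])
  } else if (scheme == "DBS78") {
    lab <- classify_dbs(s$ref, s$alt)
  } else {
    lab <- rep(NA_character_, nrow(s))
    for (i in seq_len(nrow(s))) {
      cs <- genome[[s$chrom[i]]]
      ev <- if (s$class[i] == "DEL") s$ref[i] else s$alt[i]
      len <- nchar(ev)
      wlen <- 6L * len
      if (s$class[i] == "DEL") {
        f5 <- substring(cs, max(1L, s$pos[i] - wlen), s$pos[i] - 1L)
        f3 <- substring(cs, s$pos[i] + len,
                        min(nchar(cs), s$pos[i] + len + wlen - 1L))
      } else {
        f5 <- substring(cs, max(1L, s$pos[i] - wlen + 1L), s$pos[i])
        f3 <- substring(cs, s$pos[i] + 1L,
                        min(nchar(cs), s$pos[i] + wlen))
      }
      lab[i] <- tryCatch(
        classify_indel(s$class[i], ev, f5, f3)$channel,
        error = function(e) NA_character_)
    }
  }
  excluded <- sum(w[is.na(lab)])
  counts <- tapply(w[!is.na(lab)], lab[!is.na(lab)], sum)
  .new_catalogue(counts, scheme, sample, n_excluded = as.integer(excluded))
}

#' @rdname build_catalogue
#' @return `build_catalogues()`: a named list with one catalogue per scheme.
#' @export
build_catalogues <- function(sites, genome, sample = "sample",
                             count_by = "site") {
  list(
    SBS96 = build_catalogue(sites, genome, "SBS96", sample, count_by),
    DBS78 = build_catalogue(sites, genome, "DBS78", sample, count_by),
    ID83 = build_catalogue(sites, genome, "ID83", sample, count_by)
  )
}

#' Construct a catalogue from channel counts
#'
#' @param counts Named numeric vector (channel label -> count) or a tibble
#'   with `channel` and `count`.
#' @param scheme Channel scheme.
#' @param sample Sample name.
#' @return A `plasmasig_catalogue`.
#' @export
as_catalogue <- function(counts, scheme, sample = "sample") {
  if (is.data.frame(counts)) {
    counts <- setNames(counts$count, counts$channel)
  }
  if (any(counts < 0)) abort("as_catalogue(): negative counts")
  .new_catalogue(counts, scheme, sample)
}

#' @export
print.plasmasig_catalogue <- function(x, ...) {
  cat(sprintf("<mutation catalogue: %s, %s, %g mutations (%d excluded)>\n",
              attr(x, "sample"), attr(x, "scheme"), sum(x$count),
              attr(x, "n_excluded")))
  NextMethod()
}

#' Write / read catalogue tables
#'
#' Tab-separated, channels as rows and samples as columns (the orientation of
#' COSMIC catalogue files).
#'
#' @param catalogue A `plasmasig_catalogue`.
#' @param path File path.
#' @export
write_catalogue <- function(catalogue, path) {
  out <- data.frame(Type = catalogue$channel, check.names = FALSE)
  out[[attr(catalogue, "sample") %||% "sample"]] <- catalogue$count
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalogue
#' @param sample Column to read (default: the first sample column).
#' @param scheme Channel scheme; inferred from the channels if omitted.
#' @export
read_catalogue <- function(path, sample = NULL, scheme = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  channels <- tab[[1]]
  if (is.null(scheme)) {
    scheme <- if (setequal(channels, sbs96_channels())) "SBS96"
      else if (setequal(channels, dbs78_channels())) "DBS78"
      else if (setequal(channels, id83_channels())) "ID83"
      else abort("read_catalogue(): channels match no known scheme")
  }
  sample <- sample %||% names(tab)[2]
  as_catalogue(setNames(tab[[sample]], channels), scheme, sample)
}
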