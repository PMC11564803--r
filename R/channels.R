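#' COSMIC mutation channel schemes
#'
#' Canonical, ordered channel label sets for the three COSMIC mutation
#' classification schemes: 96 single-base substitutions in trinucleotide
#' context (`SBS96`), 78 doublet-base substitutions (`DBS78`) and 83
#' insertion/deletion classes (`ID83`). Labels match the COSMIC v3.2 file
#' headers byte-for-byte, so catalogues built here join directly onto
#' downloaded signature matrices.
#'
#' @return Character vector of channel labels in canonical order.
#' @examples
#' length(sbs96_channels()) # 96
#' head(id83_channels())
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(l, r) {
      paste0(l, "[", s, "]", r)
    })))
  }))
}

# Canonical DBS78 labels. Ten canonical reference doublets; strand-equivalent
# doublets are collapsed onto this fixed set (the choice within
# reverse-complement pairs follows the COSMIC convention and is not a simple
# lexicographic rule, hence the explicit alt lists).
.dbs78_alts <- list(
  AC = c("CA", "CG", "CT", "GA", "GG", "GT", "TA", "TG", "TT"),
  AT = c("CA", "CC", "CG", "GA", "GC", "TA"),
  CC = c("AA", "AG", "AT", "GA", "GG", "GT", "TA", "TG", "TT"),
  CG = c("AT", "GC", "GT", "TA", "TC", "TT"),
  CT = c("AA", "AC", "AG", "GA", "GC", "GG", "TA", "TC", "TG"),
  GC = c("AA", "AG", "AT", "CA", "CG", "TA"),
  TA = c("AT", "CG", "CT", "GC", "GG", "GT"),
  TC = c("AA", "AG", "AT", "CA", "CG", "CT", "GA", "GG", "GT"),
  TG = c("AA", "AC", "AT", "CA", "CC", "CT", "GA", "GC", "GT"),
  TT = c("AA", "AC", "AG", "CA", "CC", "CG", "GA", "GC", "GG")
)

#' @rdname sbs96_channels
#' @export
dbs78_channels <- function() {
  unlist(lapply(names(.dbs78_alts), function(ref) {
    paste0(ref, ">", .dbs78_alts[[ref]])
  }), use.names = FALSE)
}

#' @rdname sbs96_channels
#' @export
id83_channels <- function() {
  reps <- as.character(0:5)
  c(
    paste0("1:Del:C:", reps), paste0("1:Del:T:", reps),
    paste0("1:Ins:C:", reps), paste0("1:Ins:T:", reps),
    unlist(lapply(2:5, function(l) paste0(l, ":Del:R:", reps))),
    unlist(lapply(2:5, function(l) paste0(l, ":Ins:R:", reps))),
    "2:Del:M:1", "3:Del:M:1", "3:Del:M:2",
    "4:Del:M:1", "4:Del:M:2", "4:Del:M:3",
    paste0("5:Del:M:", 1:5)
  )
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character strings (A/C/G/T/N).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
dna_revcomp <- function(x) {
  out <- vapply(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE),
                function(b) paste(rev(b), collapse = ""), character(1))
  out[is.na(x)] <- NA_character_
  out
}

#' Classify single-base substitutions into SBS96 channels
#'
#' Assigns each substitution its trinucleotide-context channel, normalised so
#' the central reference base is a pyrimidine: when the reference base is a
#' purine the reverse complement of the context and the alternate allele is
#' used.
#'
#' @param ref,alt Single reference/alternate bases (character vectors).
#' @param context The reference trinucleotide centred on the substituted base.
#' @return Character vector of SBS96 channel labels; `NA` where the context
#'   contains `N` (callers tally these as excluded).
#' @examples
#' classify_sbs("C", "T", "ACG") # "A[C>T]G"
#' classify_sbs("G", "A", "AGT") # "A[C>T]T"
#' @export
classify_sbs <- function(ref, alt, context) {
  stopifnot(length(ref) == length(alt), length(ref) == length(context))
  if (length(ref) == 0) return(character(0))
  context <- toupper(context)
  ref <- toupper(ref)
  alt <- toupper(alt)
  bad <- is.na(ref) | is.na(alt) | is.na(context) |
    nchar(context) != 3L | grepl("N", context, fixed = TRUE) |
    !ref %in% c("A", "C", "G", "T") | !alt %in% c("A", "C", "G", "T") |
    ref == alt
  centre_ok <- substr(context, 2, 2) == ref
  if (any(!centre_ok & !bad)) {
    abort("classify_sbs(): context centre does not match the reference allele")
  }
  pur <- ref %in% c("A", "G") & !bad
  context[pur] <- dna_revcomp(context[pur])
  alt[pur] <- chartr("ACGT", "TGCA", alt[pur])
  lab <- paste0(
    substr(context, 1, 1), "[", substr(context, 2, 2), ">", alt, "]",
    substr(context, 3, 3)
  )
  lab[bad] <- NA_character_
  lab
}

#' Classify doublet-base substitutions into DBS78 channels
#'
#' Collapses strand-equivalent doublets onto the canonical COSMIC set: if
#' `ref>alt` is not itself canonical, the reverse complement of both alleles
#' is used.
#'
#' @param ref,alt Two-base reference/alternate alleles.
#' @return Character vector of DBS78 labels; `NA` for alleles containing `N`
#'   or sharing a base with the reference at either position.
#' @examples
#' classify_dbs("CC", "TT") # "CC>TT"
#' classify_dbs("GG", "AA") # "CC>TT"
#' @export
classify_dbs <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  if (length(ref) == 0) return(character(0))
  ref <- toupper(ref)
  alt <- toupper(alt)
  channels <- dbs78_channels()
  lab <- paste0(ref, ">", alt)
  flip <- !lab %in% channels
  lab[flip] <- paste0(dna_revcomp(ref[flip]), ">", dna_revcomp(alt[flip]))
  bad <- is.na(ref) | is.na(alt) | nchar(ref) != 2L | nchar(alt) != 2L |
    grepl("N", paste0(ref, alt)) |
    substr(ref, 1, 1) == substr(alt, 1, 1) |
    substr(ref, 2, 2) == substr(alt, 2, 2)
  lab[!lab %in% channels] <- NA_character_
  lab[bad] <- NA_character_
  lab
}

# longest run of `motif` copies at the start of `flank`
.count_motif_copies <- function(motif, flank) {
  l <- nchar(motif)
  n <- 0L
  off <- 1L
  while (substr(flank, off, off + l - 1L) == motif && off + l - 1L <= nchar(flank)) {
    n <- n + 1L
    off <- off + l
  }
  n
}

# longest microhomology between a deleted sequence and its flanks:
# prefix of the deletion against the 3' flank, or suffix against the 5' flank
.microhomology_length <- function(seq, flank5, flank3) {
  L <- nchar(seq)
  best <- 0L
  for (k in seq_len(L - 1L)) {
    if (substr(seq, 1L, k) == substr(flank3, 1L, k)) best <- max(best, k)
    if (substr(seq, L - k + 1L, L) ==
        substr(flank5, nchar(flank5) - k + 1L, nchar(flank5))) {
      best <- max(best, k)
    }
  }
  best
}

#' Classify insertions and deletions into ID83 channels
#'
#' Implements the COSMIC v3.2 indel classification: events are split by type
#' and length class (1/2/3/4/5+), then by homopolymer length (1 bp events),
#' repeat-unit count (longer events) or, for deletions of two or more bases
#' with no repeat support, microhomology length. Events must be left-aligned
#' against the reference before classification.
#'
#' @param type `"INS"` or `"DEL"`.
#' @param seq The inserted or deleted bases (not the VCF anchor-base
#'   representation).
#' @param flank5,flank3 Reference sequence immediately 5' and 3' of the event
#'   (after removing the deleted bases, for deletions). Each flank must be at
#'   least six times the event length.
#' @return A tibble with columns `channel`, `mh_length` (microhomology length,
#'   0 for non-MH events) and `repeat_units` (copies of the event sequence in
#'   the 3' flank).
#' @examples
#' classify_indel("DEL", "T", "GCAGCA", "TTTTGA")$channel # "1:Del:T:4"
#' @export
classify_indel <- function(type, seq, flank5, flank3) {
  stopifnot(length(type) == 1L, length(seq) == 1L)
  type <- toupper(type)
  if (!type %in% c("INS", "DEL")) abort("classify_indel(): type must be INS or DEL")
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < 1L) abort("classify_indel(): empty event sequence")
  if (nchar(flank5) < 6L * L || nchar(flank3) < 6L * L) {
    abort(sprintf(
      "classify_indel(): flanks too short (need >= %d bp each side)", 6L * L))
  }
  flank5 <- toupper(flank5)
  flank3 <- toupper(flank3)
  if (grepl("N", paste0(seq, flank5, flank3))) {
    return(tibble(channel = NA_character_, mh_length = 0L, repeat_units = 0L))
  }
  n_rep <- .count_motif_copies(seq, flank3)
  len_class <- min(L, 5L)
  if (L == 1L) {
    base <- if (seq %in% c("C", "G")) "C" else "T"
    channel <- sprintf("1:%s:%s:%d", if (type == "DEL") "Del" else "Ins",
                       base, min(n_rep, 5L))
    return(tibble(channel = channel, mh_length = 0L,
                  repeat_units = as.integer(n_rep)))
  }
  if (type == "INS") {
    channel <- sprintf("%d:Ins:R:%d", len_class, min(n_rep, 5L))
    return(tibble(channel = channel, mh_length = 0L,
                  repeat_units = as.integer(n_rep)))
  }
  # deletions of >= 2 bp: repeat units take precedence over microhomology
  if (n_rep >= 1L) {
    channel <- sprintf("%d:Del:R:%d", len_class, min(n_rep, 5L))
    return(tibble(channel = channel, mh_length = 0L,
                  repeat_units = as.integer(n_rep)))
  }
  mh <- .microhomology_length(seq, flank5, flank3)
  if (mh >= 1L) {
    mh_class <- min(mh, len_class - 1L, 5L)
    channel <- sprintf("%d:Del:M:%d", len_class, mh_class)
    return(tibble(channel = channel, mh_length = as.integer(mh),
                  repeat_units = 0L))
  }
  tibble(channel = sprintf("%d:Del:R:0", len_class), mh_length = 0L,
         repeat_units = 0L)
}
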