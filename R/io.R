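# VCF v4.2 output, SAM/BAM input and SAM output for the aligned-read tibble.

.anchor_sites <- function(sites, genome) {
  n <- nrow(sites)
  pos <- sites$pos; ref <- sites$ref; alt <- sites$alt
  for (i in seq_len(n)) {
    cl <- sites$class[i]
    if (cl %in% c("SBS", "DBS")) next
    if (is.null(genome)) {
      abort("write_vcf(): a reference genome is required to anchor indels")
    }
    cs <- genome[[sites$chrom[i]]]
    if (cl == "DEL") {
      if (sites$pos[i] < 2L) abort("write_vcf(): deletion at contig start")
      anchor <- substr(cs, sites$pos[i] - 1L, sites$pos[i] - 1L)
      pos[i] <- sites$pos[i] - 1L
      ref[i] <- paste0(anchor, sites$ref[i])
      alt[i] <- anchor
    } else if (cl == "INS") {
      anchor <- substr(cs, sites$pos[i], sites$pos[i])
      ref[i] <- anchor
      alt[i] <- paste0(anchor, sites$alt[i])
    }
  }
  tibble(chrom = sites$chrom, pos = pos, ref = ref, alt = alt,
         multi = sites$multi)
}

#' Write site records to a VCF v4.2 file
#'
#' Emits one data line per site with the supporting-fragment count in the
#' `MULTI` INFO field. Indels are written in anchored VCF representation
#' (left-aligned upstream by [extract_mismatches()]); positions are 1-based.
#'
#' @param sites Site tibble from [extract_mismatches()] /
#'   [aggregate_support()].
#' @param path Output path.
#' @param sample Sample name (header metadata only).
#' @param genome Named character vector of chromosome sequences; used for
#'   contig header lines and indel anchor bases.
#' @param contigs Alternative to `genome`: named integer vector of contig
#'   lengths.
#' @return The path, invisibly.
#' @export
write_vcf <- function(sites, path, sample = "sample", genome = NULL,
                      contigs = NULL) {
  if (is.null(contigs) && !is.null(genome)) {
    contigs <- setNames(nchar(genome), names(genome))
  }
  key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt)
  if (anyDuplicated(key)) {
    abort("write_vcf(): duplicate (chrom, pos, ref, alt) records")
  }
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=plasmasig-%s",
            as.character(utils::packageVersion("plasmasig"))),
    sprintf("##sample=%s", sample),
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs),
              as.integer(contigs))
    },
    "##INFO=<ID=MULTI,Number=1,Type=Integer,Description=\"Number of distinct fragments supporting the mismatch\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- hdr
  if (nrow(sites) > 0L) {
    anc <- .anchor_sites(sites, genome)
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tMULTI=%d",
                              anc$chrom, anc$pos, anc$ref, anc$alt,
                              anc$multi))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read site records back from a VCF
#'
#' Parses a VCF (such as one written by [write_vcf()]) into the package's raw
#' site representation, classifying each record as SBS/DBS/INS/DEL from its
#' allele shapes and recovering the `MULTI` count when present.
#'
#' @param path VCF path.
#' @return Site tibble (`chrom`, `pos`, `ref`, `alt`, `class`, `multi`).
#' @export
read_vcf_sites <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_vcf_sites() requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(tibble(chrom = character(0), pos = integer(0), ref = character(0),
                  alt = character(0), class = character(0),
                  multi = integer(0)))
  }
  multi <- suppressWarnings(
    as.integer(sub(".*MULTI=(\\d+).*", "\\1", fix$INFO)))
  multi[is.na(multi)] <- 1L
  pos <- as.integer(fix$POS); ref <- toupper(fix$REF); alt <- toupper(fix$ALT)
  cls <- character(length(pos))
  rpos <- pos; rref <- ref; ralt <- alt
  for (i in seq_along(pos)) {
    if (nchar(ref[i]) == nchar(alt[i])) {
      cls[i] <- if (nchar(ref[i]) == 1L) "SBS" else "DBS"
    } else if (nchar(ref[i]) > nchar(alt[i]) &&
               startsWith(ref[i], alt[i])) {
      cls[i] <- "DEL"
      rpos[i] <- pos[i] + nchar(alt[i])
      rref[i] <- substr(ref[i], nchar(alt[i]) + 1L, nchar(ref[i]))
      ralt[i] <- ""
    } else if (nchar(alt[i]) > nchar(ref[i]) &&
               startsWith(alt[i], ref[i])) {
      cls[i] <- "INS"
      rpos[i] <- pos[i] + nchar(ref[i]) - 1L
      rref[i] <- ""
      ralt[i] <- substr(alt[i], nchar(ref[i]) + 1L, nchar(alt[i]))
    } else {
      cls[i] <- "OTHER"
    }
  }
  tibble(chrom = fix$CHROM, pos = rpos, ref = rref, alt = ralt,
         class = cls, multi = multi)
}

#' Read aligned paired-end reads from a BAM file
#'
#' Loads a coordinate-sorted BAM (MD tags required, or recomputable with
#' [compute_md()]) into the package's aligned-read tibble.
#'
#' @param path BAM path (index not required).
#' @return Aligned-read tibble (schema of [simulate_clean_reads()]).
#' @export
read_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("read_alignments() requires the Rsamtools package")
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq",
             "qual", "isize"),
    tag = "MD")
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  flag <- b$flag
  tibble(
    qname = b$qname,
    chrom = as.character(b$rname),
    pos = b$pos,
    mate = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L),
    cigar = b$cigar,
    md = as.character(b$tag$MD),
    seq = as.character(b$seq),
    qual = as.character(b$qual),
    mapq = b$mapq,
    fraglen = b$isize,
    secondary = bitwAnd(flag, 256L) > 0L,
    duplicate = bitwAnd(flag, 1024L) > 0L,
    proper = bitwAnd(flag, 2L) > 0L
  )
}

#' Write an aligned-read tibble as SAM text
#'
#' Serialises the in-memory read set to a plain-text SAM file (convertible to
#' BAM with samtools or `Rsamtools::asBam()`); mate 2 is written as the
#' reverse-strand read of an FR pair.
#'
#' @param reads Aligned-read tibble.
#' @param path Output path (`.sam`).
#' @param contigs Named integer vector of contig lengths (or a genome vector
#'   via `genome`).
#' @param genome Optional named character vector of chromosome sequences.
#' @return The path, invisibly.
#' @export
write_sam <- function(reads, path, contigs = NULL, genome = NULL) {
  if (is.null(contigs)) {
    if (is.null(genome)) abort("write_sam(): contigs or genome required")
    contigs <- setNames(nchar(genome), names(genome))
  }
  reads <- reads[order(reads$chrom, reads$pos), , drop = FALSE]
  mate_pos <- reads$pos
  other <- match(paste(reads$qname, 3L - reads$mate),
                 paste(reads$qname, reads$mate))
  mate_pos <- ifelse(is.na(other), reads$pos, reads$pos[other])
  flag <- 1L +
    ifelse(reads$proper, 2L, 0L) +
    ifelse(reads$mate == 2L, 16L + 128L, 32L + 64L) +
    ifelse(reads$secondary, 256L, 0L) +
    ifelse(reads$duplicate, 1024L, 0L)
  tlen <- ifelse(reads$mate == 1L, abs(reads$fraglen), -abs(reads$fraglen))
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs)),
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t%s\t%s\tMD:Z:%s",
            reads$qname, flag, reads$chrom, reads$pos, reads$mapq,
            reads$cigar, mate_pos, tlen, reads$seq, reads$qual, reads$md)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write and read FASTA genomes
#'
#' Thin wrappers over Biostrings for the named-character-vector genome
#' representation used throughout the package.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path FASTA path.
#' @return `read_genome()` returns a named character vector.
#' @export
write_genome <- function(genome, path) {
  x <- Biostrings::DNAStringSet(unlist(genome))
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
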