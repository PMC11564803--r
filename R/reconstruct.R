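# CIGAR / MD reconstruction of mismatches.
#
# Raw event representation used throughout extraction:
#   SBS: pos = substituted base, ref/alt single bases
#   DBS: pos = first base of the doublet, ref/alt two bases
#   DEL: pos = first deleted base, ref = deleted bases, alt = ""
#   INS: pos = reference base immediately 5' of the insertion, ref = "",
#        alt = inserted bases
# Anchored VCF-style alleles are produced only at output time.

.parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "" || cigar == "*") {
    abort("unusable CIGAR string", class = "plasmasig_malformed_record")
  }
  m <- gregexpr("\\d+|[MIDNSHP=X]", cigar)[[1]]
  tok <- regmatches(cigar, list(m))[[1]]
  lens <- suppressWarnings(as.integer(tok[c(TRUE, FALSE)]))
  ops <- tok[c(FALSE, TRUE)]
  if (length(lens) != length(ops) || anyNA(lens) ||
      nchar(cigar) != sum(nchar(tok))) {
    abort(sprintf("malformed CIGAR '%s'", cigar),
          class = "plasmasig_malformed_record")
  }
  list(ops = ops, lens = lens)
}

.parse_md <- function(md, qname = "?") {
  if (is.null(md) || length(md) != 1L || is.na(md) || md == "") {
    abort(sprintf("read '%s' is missing its MD tag", qname),
          class = "plasmasig_missing_tag")
  }
  m <- gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md)[[1]]
  tok <- regmatches(md, list(m))[[1]]
  if (nchar(md) != sum(nchar(tok))) {
    abort(sprintf("malformed MD tag '%s' on read '%s'", md, qname),
          class = "plasmasig_malformed_record")
  }
  tok
}

.qual_ints <- function(qual) {
  if (is.na(qual) || qual == "" || qual == "*") return(integer(0))
  utf8ToInt(qual) - 33L
}

# Reconstruct raw mismatches for one aligned read.
# Returns a tibble: gpos, read_off, ref, alt, class, bq.
.reconstruct_one <- function(pos, cigar, md, seq, qual, qname = "?") {
  cg <- .parse_cigar(cigar)
  mdtok <- .parse_md(md, qname)
  quals <- .qual_ints(qual)
  nread <- nchar(seq)

  md_i <- 1L          # next MD token
  md_rem <- 0L        # remaining matched bases in current numeric token
  next_md <- function() {
    if (md_i > length(mdtok)) {
      abort(sprintf("MD tag exhausted before CIGAR on read '%s'", qname),
            class = "plasmasig_malformed_record")
    }
    t <- mdtok[[md_i]]
    md_i <<- md_i + 1L
    t
  }

  gpos <- integer(0); read_off <- integer(0)
  ref <- character(0); alt <- character(0)
  cls <- character(0); bq <- integer(0)

  q <- 1L   # 1-based read offset
  g <- pos  # genome position of next aligned base

  for (k in seq_along(cg$ops)) {
    op <- cg$ops[k]; len <- cg$lens[k]
    if (op %in% c("M", "=", "X")) {
      done <- 0L
      while (done < len) {
        if (md_rem > 0L) {
          step <- min(md_rem, len - done)
          md_rem <- md_rem - step
          done <- done + step
          q <- q + step
          g <- g + step
          next
        }
        t <- next_md()
        if (grepl("^[0-9]+$", t)) {
          md_rem <- as.integer(t)
        } else if (startsWith(t, "^")) {
          abort(sprintf(
            "MD deletion where CIGAR has aligned bases on read '%s'", qname),
            class = "plasmasig_malformed_record")
        } else {
          if (q > nread) {
            abort(sprintf("MD tag runs past read '%s'", qname),
                  class = "plasmasig_malformed_record")
          }
          gpos <- c(gpos, g)
          read_off <- c(read_off, q)
          ref <- c(ref, t)
          alt <- c(alt, substr(seq, q, q))
          cls <- c(cls, "SBS")
          bq <- c(bq, if (length(quals) >= q) quals[q] else NA_integer_)
          q <- q + 1L
          g <- g + 1L
          done <- done + 1L
        }
      }
    } else if (op == "I") {
      ins <- substr(seq, q, q + len - 1L)
      insq <- if (length(quals) >= q + len - 1L) {
        min(quals[q:(q + len - 1L)])
      } else NA_integer_
      gpos <- c(gpos, g - 1L)
      read_off <- c(read_off, q)
      ref <- c(ref, "")
      alt <- c(alt, ins)
      cls <- c(cls, "INS")
      bq <- c(bq, insq)
      q <- q + len
    } else if (op == "D") {
      # skip any zero-length match tokens before the deletion marker
      while (md_rem == 0L && md_i <= length(mdtok) &&
             grepl("^[0-9]+$", mdtok[[md_i]])) {
        md_rem <- as.integer(next_md())
      }
      if (md_rem > 0L) {
        abort(sprintf("CIGAR deletion disagrees with MD on read '%s'", qname),
              class = "plasmasig_malformed_record")
      }
      t <- next_md()
      if (!startsWith(t, "^") || nchar(t) - 1L != len) {
        abort(sprintf("CIGAR deletion disagrees with MD on read '%s'", qname),
              class = "plasmasig_malformed_record")
      }
      delseq <- substr(t, 2L, nchar(t))
      fl <- c(if (q > 1L && length(quals) >= q - 1L) quals[q - 1L],
              if (length(quals) >= q) quals[q])
      gpos <- c(gpos, g)
      read_off <- c(read_off, q)
      ref <- c(ref, delseq)
      alt <- c(alt, "")
      cls <- c(cls, "DEL")
      bq <- c(bq, if (length(fl)) min(fl) else NA_integer_)
      g <- g + len
    } else if (op %in% c("S")) {
      q <- q + len
    } else if (op %in% c("N")) {
      g <- g + len
    } # H, P consume nothing
  }
  # trailing zero-length MD match tokens are legal
  while (md_i <= length(mdtok) && grepl("^[0-9]+$", mdtok[[md_i]]) &&
         as.integer(mdtok[[md_i]]) == 0L) {
    md_i <- md_i + 1L
  }
  if (md_rem > 0L || md_i <= length(mdtok)) {
    abort(sprintf("MD tag longer than CIGAR alignment on read '%s'", qname),
          class = "plasmasig_malformed_record")
  }
  tibble(
    gpos = gpos, read_off = read_off, ref = ref, alt = alt,
    class = cls, bq = as.integer(bq)
  )
}

# Merge adjacent substitutions on one read into doublets; runs of three or
# more adjacent substitutions are discarded as likely artefacts.
.merge_dbs <- function(mm) {
  if (nrow(mm) < 2L) return(list(mm = mm, n_long_runs = 0L))
  sub <- mm$class == "SBS"
  o <- order(!sub, mm$gpos)
  mm <- mm[o, ]
  sub <- mm$class == "SBS"
  nsub <- sum(sub)
  if (nsub < 2L) return(list(mm = mm, n_long_runs = 0L))
  s <- mm[sub, ]
  newrun <- c(TRUE, diff(s$gpos) != 1L | diff(s$read_off) != 1L)
  run <- cumsum(newrun)
  rl <- tabulate(run)
  keep_single <- rl[run] == 1L
  out <- s[keep_single, ]
  n_long <- 0L
  for (r in which(rl == 2L)) {
    i <- which(run == r)
    out <- bind_rows(out, tibble(
      gpos = s$gpos[i[1]], read_off = s$read_off[i[1]],
      ref = paste0(s$ref[i[1]], s$ref[i[2]]),
      alt = paste0(s$alt[i[1]], s$alt[i[2]]),
      class = "DBS", bq = min(s$bq[i[1]], s$bq[i[2]])
    ))
  }
  n_long <- sum(rl >= 3L)
  list(mm = bind_rows(out, mm[!sub, ]) %>% arrange(.data$gpos),
       n_long_runs = n_long)
}

#' Reconstruct mismatches of one aligned read from its MD and CIGAR tags
#'
#' Recovers every position where the read disagrees with the reference:
#' substitutions (adjacent pairs merged into doublet events, runs of three or
#' more discarded as artefacts), insertions and deletions. Soft-clipped and
#' padded segments contribute nothing. The reference alleles come from the MD
#' tag itself; an optional reference window is checked for consistency.
#'
#' @param record A list or one-row data frame with elements `pos` (1-based
#'   leftmost aligned position), `cigar`, `md`, `seq`, `qual` (Phred+33
#'   string) and optionally `qname`.
#' @param reference_window Optional reference sequence starting at `pos`,
#'   used to cross-check the reconstruction.
#' @return A tibble with one row per mismatch event: `gpos` (1-based genome
#'   position), `read_off`, `ref`, `alt`, `class` (`SBS`/`DBS`/`INS`/`DEL`)
#'   and `bq` (base quality; summed later by overlap consensus).
#' @examples
#' reconstruct_mismatches(list(pos = 10L, cigar = "4M", md = "2G1",
#'                             seq = "ACTT", qual = "IIII"))
#' @export
reconstruct_mismatches <- function(record, reference_window = NULL) {
  qname <- if (!is.null(record$qname)) record$qname else "?"
  mm <- .reconstruct_one(record$pos, record$cigar, record$md,
                         record$seq, record$qual, qname)
  if (!is.null(reference_window)) {
    for (i in seq_len(nrow(mm))) {
      if (mm$class[i] %in% c("SBS", "DBS", "DEL")) {
        off <- mm$gpos[i] - record$pos + 1L
        want <- substr(reference_window, off, off + nchar(mm$ref[i]) - 1L)
        if (nchar(want) == nchar(mm$ref[i]) && want != mm$ref[i]) {
          abort(sprintf(
            "MD-derived reference allele disagrees with the reference window on read '%s'",
            qname), class = "plasmasig_malformed_record")
        }
      }
    }
  }
  res <- .merge_dbs(mm)
  res$mm
}

#' Recompute an MD tag from the read and the reference
#'
#' Utility for records whose aligner did not emit MD tags: reconstructs the
#' tag from the read sequence, its CIGAR string and the reference window
#' covering the alignment span.
#'
#' @param seq Read sequence.
#' @param cigar CIGAR string.
#' @param reference_window Reference sequence starting at the leftmost
#'   aligned position, covering at least the aligned span.
#' @return The MD tag string.
#' @export
compute_md <- function(seq, cigar, reference_window) {
  cg <- .parse_cigar(cigar)
  q <- 1L; r <- 1L
  parts <- character(0)
  run <- 0L
  flush <- function() { parts <<- c(parts, as.character(run)); run <<- 0L }
  for (k in seq_along(cg$ops)) {
    op <- cg$ops[k]; len <- cg$lens[k]
    if (op %in% c("M", "=", "X")) {
      for (i in seq_len(len)) {
        rb <- substr(reference_window, r, r)
        qb <- substr(seq, q, q)
        if (rb == "") {
          abort("reference window shorter than the alignment span",
                class = "plasmasig_malformed_record")
        }
        if (rb == qb) run <- run + 1L else { flush(); parts <- c(parts, rb) }
        q <- q + 1L; r <- r + 1L
      }
    } else if (op == "I") {
      q <- q + len
    } else if (op == "D") {
      flush()
      parts <- c(parts, paste0("^", substr(reference_window, r, r + len - 1L)))
      r <- r + len
    } else if (op == "S") {
      q <- q + len
    } else if (op == "N") {
      r <- r + len
    }
  }
  flush()
  paste(parts, collapse = "")
}

#' Left-align an indel against the reference
#'
#' Shifts an insertion or deletion to its leftmost equivalent representation,
#' the normal form used for germline lookup, ID83 classification and VCF
#' output.
#'
#' @param pos For deletions, the position of the first deleted base; for
#'   insertions, the reference position immediately 5' of the insertion.
#' @param seq The deleted or inserted bases.
#' @param type `"DEL"` or `"INS"`.
#' @param chromseq Reference chromosome sequence (single string).
#' @return A list with the shifted `pos` and `seq`.
#' @export
left_align_indel <- function(pos, seq, type, chromseq) {
  L <- nchar(seq)
  if (type == "DEL") {
    while (pos > 1L &&
           substr(chromseq, pos - 1L, pos - 1L) == substr(seq, L, L)) {
      pos <- pos - 1L
      seq <- substr(chromseq, pos, pos + L - 1L)
    }
  } else {
    while (pos >= 1L &&
           substr(chromseq, pos, pos) == substr(seq, L, L)) {
      seq <- paste0(substr(chromseq, pos, pos), substr(seq, 1L, L - 1L))
      pos <- pos - 1L
    }
  }
  list(pos = pos, seq = seq)
}
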