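# Extraction driver: reconstruct -> consensus -> filters -> site aggregation.

.ref_span <- function(cigar, seqlen) {
  allm <- grepl("^\\d+M$", cigar)
  span <- integer(length(cigar))
  span[allm] <- seqlen[allm]
  for (i in which(!allm)) {
    cg <- .parse_cigar(cigar[i])
    span[i] <- sum(cg$lens[cg$ops %in% c("M", "D", "N", "=", "X")])
  }
  span
}

# base and quality of a read at a genome position, via its CIGAR
.read_base_at <- function(gpos, pos, cigar, seq, qual) {
  cg <- .parse_cigar(cigar)
  q <- 1L; g <- pos
  for (k in seq_along(cg$ops)) {
    op <- cg$ops[k]; len <- cg$lens[k]
    if (op %in% c("M", "=", "X")) {
      if (gpos < g + len) {
        off <- q + (gpos - g)
        return(list(base = substr(seq, off, off),
                    q = utf8ToInt(substr(qual, off, off)) - 33L))
      }
      q <- q + len; g <- g + len
    } else if (op == "I") {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      if (gpos < g + len) return(list(base = "", q = NA_integer_))
      g <- g + len
    } else if (op == "S") {
      q <- q + len
    }
  }
  list(base = "", q = NA_integer_)
}

#' Merge mate mismatches by overlap consensus
#'
#' Reconciles the mismatches of one fragment's two mates inside their
#' alignment overlap. Agreeing mismatches carry the sum of the two base
#' qualities; at disagreeing positions the higher-quality base is kept with
#' its quality reduced by half the lower quality (ties keep mate 1's base).
#' Outside the overlap, mismatches pass through unchanged. With
#' `only_overlap`, non-overlap mismatches are dropped; with `strict_overlap`
#' additionally enabled, disagreeing positions are dropped entirely.
#'
#' This is the single-fragment surface of the consensus step;
#' [extract_mismatches()] applies the same rules vectorised over a whole read
#' set.
#'
#' @param fragment_reads Tibble of the (<= 2) mate records of one fragment
#'   (columns as in [simulate_clean_reads()]).
#' @param only_overlap,strict_overlap Consensus stringency flags.
#' @return Tibble of consensus mismatches with columns `gpos`, `ref`, `alt`,
#'   `class`, `bq` (combined), `bq_min` (lowest supporting single-read
#'   quality) and `in_overlap`.
#' @export
consensus_merge <- function(fragment_reads, only_overlap = FALSE,
                            strict_overlap = FALSE) {
  stopifnot(nrow(fragment_reads) >= 1L, nrow(fragment_reads) <= 2L,
            length(unique(fragment_reads$qname)) == 1L)
  mm <- purrr::map_dfr(seq_len(nrow(fragment_reads)), function(i) {
    r <- fragment_reads[i, ]
    out <- .reconstruct_one(r$pos, r$cigar, r$md, r$seq, r$qual, r$qname)
    out <- .merge_dbs(out)$mm
    out$mate <- r$mate
    out$qname <- r$qname
    out
  })
  cfg <- filter_config(min_mapq = 0, min_bq = 0, min_avg_bq = 0,
                       min_mismatches = 0, max_mismatches = Inf,
                       consensus = TRUE,
                       only_overlap = only_overlap,
                       strict_overlap = strict_overlap)
  .consensus(mm, fragment_reads, cfg)$mm
}

# Vectorised consensus over a raw mismatch table.
# mm: qname, mate, gpos, read_off, ref, alt, class, bq
# reads: the kept reads of fragments appearing in mm
.consensus <- function(mm, reads, config) {
  tally <- c(dropped_only_overlap = 0L, dropped_strict = 0L,
             dropped_consensus_lost = 0L)
  if (nrow(mm) == 0L) {
    mm$bq_min <- integer(0)
    mm$in_overlap <- logical(0)
    return(list(mm = mm, tally = tally))
  }
  reads <- reads[reads$qname %in% unique(mm$qname), ]
  span <- .ref_span(reads$cigar, nchar(reads$seq))
  meta <- tibble(qname = reads$qname, mate = reads$mate, pos = reads$pos,
                 end = reads$pos + span - 1L, seq = reads$seq,
                 qual = reads$qual, cigar = reads$cigar,
                 allm = grepl("^\\d+M$", reads$cigar))
  m1 <- meta[meta$mate == 1L, ]
  m2 <- meta[meta$mate == 2L, ]
  i1 <- match(mm$qname, m1$qname)
  i2 <- match(mm$qname, m2$qname)
  pos1 <- m1$pos[i1]; end1 <- m1$end[i1]
  pos2 <- m2$pos[i2]; end2 <- m2$end[i2]
  o_lo <- pmax(pos1, pos2); o_hi <- pmin(end1, end2)
  has_ovl <- !is.na(o_lo) & o_lo <= o_hi
  ev_end <- mm$gpos + pmax(nchar(mm$ref), 1L) - 1L
  in_ovl <- has_ovl & mm$gpos >= o_lo & ev_end <= o_hi
  in_ovl[is.na(in_ovl)] <- FALSE

  out_of <- mm[!in_ovl, , drop = FALSE]
  out_of$bq_min <- out_of$bq
  out_of$in_overlap <- FALSE
  if (config$only_overlap) {
    tally["dropped_only_overlap"] <- nrow(out_of)
    out_of <- out_of[0, , drop = FALSE]
  }

  inn <- mm[in_ovl, , drop = FALSE]
  if (nrow(inn) == 0L) {
    return(list(mm = out_of, tally = tally))
  }
  key <- paste(inn$qname, inn$gpos)
  cnt <- table(key)[key]
  paired <- as.integer(cnt) == 2L

  res <- list()

  # both mates report an event at this position
  if (any(paired)) {
    p <- inn[paired, , drop = FALSE]
    p <- p[order(p$qname, p$gpos, p$mate), , drop = FALSE]
    a <- p[seq(1, nrow(p), 2), , drop = FALSE]
    b <- p[seq(2, nrow(p), 2), , drop = FALSE]
    same <- a$ref == b$ref & a$alt == b$alt & a$class == b$class
    agree <- a[same, , drop = FALSE]
    agree$bq_min <- pmin(a$bq[same], b$bq[same])
    agree$bq <- a$bq[same] + b$bq[same]
    agree$in_overlap <- TRUE
    res$agree <- agree
    if (any(!same)) {
      if (config$strict_overlap) {
        tally["dropped_strict"] <- tally["dropped_strict"] + sum(!same)
      } else {
        da <- a[!same, , drop = FALSE]; db <- b[!same, , drop = FALSE]
        a_wins <- da$bq >= db$bq   # tie keeps mate 1
        win <- da
        win[!a_wins, ] <- db[!a_wins, ]
        lo <- pmin(da$bq, db$bq)
        win$bq_min <- win$bq
        win$bq <- pmax(da$bq, db$bq) - lo / 2
        win$in_overlap <- TRUE
        res$disagree_pair <- win
      }
    }
  }

  # only one mate reports an event; the other shows its aligned base
  if (any(!paired)) {
    s <- inn[!paired, , drop = FALSE]
    j1 <- match(s$qname, m1$qname)
    j2 <- match(s$qname, m2$qname)
    use2 <- s$mate == 1L
    o_pos <- ifelse(use2, m2$pos[j2], m1$pos[j1])
    o_seq <- ifelse(use2, m2$seq[j2], m1$seq[j1])
    o_qual <- ifelse(use2, m2$qual[j2], m1$qual[j1])
    o_allm <- ifelse(use2, m2$allm[j2], m1$allm[j1])
    off <- s$gpos - o_pos + 1L
    obase <- substr(o_seq, off, off)
    qch <- substr(o_qual, off, off)
    oq <- rep(0L, length(qch))
    okq <- nchar(qch) == 1L
    if (any(okq)) {
      oq[okq] <- utf8ToInt(paste(qch[okq], collapse = "")) - 33L
    }
    for (j in which(!o_allm)) {
      ba <- .read_base_at(s$gpos[j], o_pos[j],
                          ifelse(use2[j], m2$cigar[j2[j]], m1$cigar[j1[j]]),
                          o_seq[j], o_qual[j])
      obase[j] <- ba$base
      oq[j] <- if (is.na(ba$q)) 0L else ba$q
    }
    if (config$strict_overlap) {
      tally["dropped_strict"] <- tally["dropped_strict"] + nrow(s)
    } else {
      # the other mate carries the reference (or at least a different
      # representation): quality contest, ties keep mate 1's base
      alt_wins <- s$bq > oq | (s$bq == oq & s$mate == 1L)
      kept <- s[alt_wins, , drop = FALSE]
      oqk <- oq[alt_wins]
      kept$bq_min <- kept$bq
      kept$bq <- kept$bq - oqk / 2
      kept$in_overlap <- TRUE
      tally["dropped_consensus_lost"] <-
        tally["dropped_consensus_lost"] + sum(!alt_wins)
      res$single <- kept
    }
  }

  merged <- bind_rows(res)
  merged <- bind_rows(merged, out_of)
  list(mm = merged, tally = tally)
}

#' Aggregate per-fragment mismatches into site records
#'
#' Collapses identical `(chrom, pos, ref, alt)` events across fragments into
#' one record whose `multi` field counts the distinct supporting fragments.
#'
#' @param mismatches Tibble of retained per-fragment mismatches (must carry
#'   `qname`).
#' @param min_support Optional read-depth filter: minimum number of distinct
#'   supporting fragments (default 1).
#' @return Site-level tibble sorted by chromosome and position with columns
#'   `chrom`, `pos`, `ref`, `alt`, `class`, `multi`, `bq` (best combined
#'   quality observed).
#' @export
aggregate_support <- function(mismatches, min_support = 1) {
  if (nrow(mismatches) == 0L) {
    return(tibble(chrom = character(0), pos = integer(0), ref = character(0),
                  alt = character(0), class = character(0), multi = integer(0),
                  bq = numeric(0)))
  }
  mismatches %>%
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt, .data$class) %>%
    summarise(multi = n_distinct(.data$qname), bq = max(.data$bq),
              .groups = "drop") %>%
    filter(.data$multi >= min_support) %>%
    arrange(.data$chrom, .data$pos)
}

#' Extract high-confidence somatic mismatches from aligned reads
#'
#' The full extraction stack: per-read mismatch reconstruction from MD/CIGAR
#' tags, read-pair overlap consensus, fragment- and mismatch-level filters,
#' optional germline removal, and aggregation into site records with
#' supporting-fragment counts.
#'
#' @param reads Aligned read tibble with columns `qname`, `chrom`, `pos`,
#'   `mate`, `cigar`, `md`, `seq`, `qual`, `mapq`, `fraglen`, `secondary`,
#'   `duplicate`, `proper` (the schema produced by [simulate_clean_reads()]
#'   and [read_alignments()]).
#' @param config A [filter_config()] or [filter_preset()].
#' @param germline Optional [germline_store()].
#' @param genome Optional named character vector of chromosome sequences;
#'   required to left-align indels before germline lookup and output.
#' @param sample Sample name recorded in the result.
#' @return A `plasmasig_extract` object: a list with `sites` (the site-level
#'   tibble, see [aggregate_support()]), `mismatches` (retained per-fragment
#'   events) and `report` (run tallies, including `filtered_bases`, the
#'   number of sequenced bases on fragments surviving the fragment-level
#'   filters). `tidy()` returns the site tibble.
#' @export
extract_mismatches <- function(reads, config = filter_config(),
                               germline = NULL, genome = NULL,
                               sample = "sample") {
  stopifnot(is.data.frame(reads))
  rep_tally <- list(sample = sample)
  rep_tally$reads_seen <- nrow(reads)
  rep_tally$fragments_seen <- n_distinct(reads$qname)

  n_secondary <- sum(reads$secondary)
  reads <- reads[!reads$secondary, , drop = FALSE]

  fs <- apply_fragment_filters(reads, config)
  rej <- table(fs$reason[!fs$keep])
  keep_q <- fs$qname[fs$keep]
  reads <- reads[reads$qname %in% keep_q, , drop = FALSE]

  # reconstruct raw mismatches on candidate reads: a vectorised fast path for
  # substitution-only all-match reads, the general walker for the rest
  cand <- grepl("[A-Z^]", reads$md) | grepl("[IDX]", reads$cigar)
  simple <- cand & grepl("^\\d+M$", reads$cigar) & !grepl("^", reads$md,
                                                          fixed = TRUE)
  complex_ <- cand & !simple
  n_long_runs <- 0L
  raw_counts <- integer(nrow(reads))
  parts <- list()
  if (any(simple)) {
    si <- which(simple)
    toks <- regmatches(reads$md[si], gregexpr("[0-9]+|[A-Z]", reads$md[si]))
    nmm <- integer(length(si))
    offs <- vector("list", length(si))
    refs <- vector("list", length(si))
    for (k in seq_along(si)) {
      tk <- toks[[k]]
      isnum <- grepl("^[0-9]", tk)
      vals <- rep(1L, length(tk))
      vals[isnum] <- as.integer(tk[isnum])
      ends <- cumsum(vals)
      if (sum(nchar(tk)) != nchar(reads$md[si[k]]) ||
          ends[length(ends)] != nchar(reads$seq[si[k]])) {
        abort(sprintf("MD tag disagrees with read length on read '%s'",
                      reads$qname[si[k]]),
              class = "plasmasig_malformed_record")
      }
      offs[[k]] <- ends[!isnum]
      refs[[k]] <- tk[!isnum]
      nmm[k] <- sum(!isnum)
    }
    raw_counts[si] <- nmm
    ridx <- rep.int(si, nmm)
    off <- unlist(offs)
    refb <- unlist(refs)
    gpos <- reads$pos[ridx] + off - 1L
    alt <- substr(reads$seq[ridx], off, off)
    bq <- utf8ToInt(paste(substr(reads$qual[ridx], off, off),
                          collapse = "")) - 33L
    sm <- tibble(gpos = gpos, read_off = off, ref = refb, alt = alt,
                 class = "SBS", bq = as.numeric(bq),
                 qname = reads$qname[ridx], mate = reads$mate[ridx],
                 chrom = reads$chrom[ridx])
    # doublet merging across the flat table (within reads)
    if (nrow(sm) > 1L) {
      uid <- paste(sm$qname, sm$mate)
      o <- order(uid, sm$gpos)
      sm <- sm[o, ]
      uid <- uid[o]
      newrun <- c(TRUE, diff(sm$gpos) != 1L) | c(TRUE, uid[-1] != uid[-length(uid)])
      run <- cumsum(newrun)
      rl <- tabulate(run)
      keep1 <- rl[run] == 1L
      pairs_first <- rl[run] == 2L & !duplicated(run)
      pairs_second <- rl[run] == 2L & duplicated(run)
      dbs <- sm[pairs_first, , drop = FALSE]
      if (nrow(dbs)) {
        second <- sm[pairs_second, , drop = FALSE]
        dbs$ref <- paste0(dbs$ref, second$ref)
        dbs$alt <- paste0(dbs$alt, second$alt)
        dbs$class <- "DBS"
        dbs$bq <- pmin(dbs$bq, second$bq)
      }
      n_long_runs <- n_long_runs + sum(rl >= 3L)
      sm <- bind_rows(sm[keep1, , drop = FALSE], dbs)
    }
    parts$simple <- sm
  }
  if (any(complex_)) {
    idx <- which(complex_)
    cparts <- vector("list", length(idx))
    for (k in seq_along(idx)) {
      i <- idx[k]
      one <- .reconstruct_one(reads$pos[i], reads$cigar[i], reads$md[i],
                              reads$seq[i], reads$qual[i], reads$qname[i])
      raw_counts[i] <- nrow(one)
      merged <- .merge_dbs(one)
      n_long_runs <- n_long_runs + merged$n_long_runs
      one <- merged$mm
      if (nrow(one)) {
        one$bq <- as.numeric(one$bq)
        one$qname <- reads$qname[i]
        one$mate <- reads$mate[i]
        one$chrom <- reads$chrom[i]
        cparts[[k]] <- one
      }
    }
    parts$complex <- bind_rows(cparts)
  }
  mm_raw <- bind_rows(parts)
  if (nrow(mm_raw) == 0L) {
    mm_raw <- tibble(gpos = integer(0), read_off = integer(0),
                     ref = character(0), alt = character(0),
                     class = character(0), bq = numeric(0),
                     qname = character(0), mate = integer(0),
                     chrom = character(0))
  }

  # per-read mismatch-count bounds: a read over the maximum invalidates its
  # fragment; a read under the minimum just contributes nothing
  over_q <- unique(reads$qname[raw_counts > config$max_mismatches])
  under <- raw_counts < config$min_mismatches
  if (length(over_q)) {
    reads_over <- reads$qname %in% over_q
    mm_raw <- mm_raw[!mm_raw$qname %in% over_q, , drop = FALSE]
    reads <- reads[!reads_over, , drop = FALSE]
    under <- under[!reads_over]
  }
  if (any(under)) {
    drop_reads <- paste(reads$qname[under], reads$mate[under])
    mm_raw <- mm_raw[!paste(mm_raw$qname, mm_raw$mate) %in% drop_reads, ,
                     drop = FALSE]
  }
  rej <- c(rej, `mismatch count` = length(over_q))

  filtered_bases <- sum(nchar(reads$seq))

  if (config$consensus) {
    cons <- .consensus(mm_raw, reads, config)
    mm <- cons$mm
  } else {
    mm <- mm_raw
    mm$bq_min <- mm$bq
    mm$in_overlap <- FALSE
    cons <- list(tally = c(dropped_only_overlap = 0L, dropped_strict = 0L,
                           dropped_consensus_lost = 0L))
  }
  n_after_consensus <- nrow(mm)

  # mismatch-level quality thresholds (inclusive)
  drop_rbq <- mm$bq_min < config$min_read_bq
  n_drop_rbq <- sum(drop_rbq)
  mm <- mm[!drop_rbq, , drop = FALSE]
  drop_bq <- mm$bq < config$min_bq
  n_drop_bq <- sum(drop_bq)
  mm <- mm[!drop_bq, , drop = FALSE]

  mm <- rename(mm, pos = "gpos")

  n_drop_wl <- 0L; n_drop_bl <- 0L
  if (!is.null(config$whitelist) && nrow(mm)) {
    inw <- .in_intervals(mm$chrom, mm$pos, config$whitelist)
    n_drop_wl <- sum(!inw)
    mm <- mm[inw, , drop = FALSE]
  }
  if (!is.null(config$blacklist) && nrow(mm)) {
    inb <- .in_intervals(mm$chrom, mm$pos, config$blacklist)
    n_drop_bl <- sum(inb)
    mm <- mm[!inb, , drop = FALSE]
  }

  # left-align indels before germline lookup and output
  if (!is.null(genome) && nrow(mm)) {
    ind <- which(mm$class %in% c("INS", "DEL"))
    for (i in ind) {
      cs <- genome[[mm$chrom[i]]]
      if (is.null(cs) || is.na(cs)) next
      if (mm$class[i] == "DEL") {
        la <- left_align_indel(mm$pos[i], mm$ref[i], "DEL", cs)
        mm$pos[i] <- la$pos; mm$ref[i] <- la$seq
      } else {
        la <- left_align_indel(mm$pos[i], mm$alt[i], "INS", cs)
        mm$pos[i] <- la$pos; mm$alt[i] <- la$seq
      }
    }
  }

  n_before_germ <- nrow(mm)
  mm <- filter_germline(mm, germline)
  n_drop_germ <- n_before_germ - nrow(mm)

  # attach fragment length for fragment-size-aware downstream summaries
  if (nrow(mm)) {
    fl <- reads %>% distinct(.data$qname, .keep_all = TRUE) %>%
      select("qname", "fraglen")
    mm <- left_join(mm, fl, by = "qname")
    mm$fraglen <- abs(mm$fraglen)
  } else {
    mm$fraglen <- integer(0)
  }

  sites <- aggregate_support(mm, min_support = config$min_support)

  report <- list(
    sample = sample,
    reads_seen = rep_tally$reads_seen,
    fragments_seen = rep_tally$fragments_seen,
    secondary_reads_dropped = n_secondary,
    fragments_rejected = as.list(rej),
    fragments_kept = n_distinct(reads$qname),
    filtered_bases = filtered_bases,
    mismatches_raw = sum(raw_counts),
    long_substitution_runs_dropped = n_long_runs,
    consensus = as.list(cons$tally),
    mismatches_after_consensus = n_after_consensus,
    dropped_read_bq = n_drop_rbq,
    dropped_combined_bq = n_drop_bq,
    dropped_whitelist = n_drop_wl,
    dropped_blacklist = n_drop_bl,
    dropped_germline = n_drop_germ,
    mismatches_retained = nrow(mm),
    sites = nrow(sites),
    class_counts = as.list(table(sites$class))
  )
  structure(list(sites = sites, mismatches = as_tibble(mm), report = report),
            class = "plasmasig_extract")
}

#' @export
print.plasmasig_extract <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<plasmasig extraction: %s>\n  fragments: %d seen, %d kept\n  mismatches: %d raw -> %d retained at %d sites\n  filtered bases: %.3g\n",
    r$sample, r$fragments_seen, r$fragments_kept, r$mismatches_raw,
    r$mismatches_retained, r$sites, r$filtered_bases))
  invisible(x)
}

#' @export
#' @method tidy plasmasig_extract
tidy.plasmasig_extract <- function(x, ...) x$sites

#' @export
#' @method glance plasmasig_extract
glance.plasmasig_extract <- function(x, ...) {
  r <- x$report
  tibble(sample = r$sample, fragments_seen = r$fragments_seen,
         fragments_kept = r$fragments_kept,
         mismatches_retained = r$mismatches_retained,
         sites = r$sites, filtered_bases = r$filtered_bases)
}
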