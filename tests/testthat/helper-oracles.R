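# Independent oracles and fixture builders. Everything here is deliberately
# written as plain, slow, obviously-correct code, separate from the package's
# implementation paths.

BASES <- c("A", "C", "G", "T")

rc_oracle <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# ---- fuzzed aligned fragment with known truth -------------------------------
# Builds one read from a reference window by walking a randomly chosen gap
# structure, and derives CIGAR/MD plus the expected mismatch list directly
# from that truth (independently of the package's reconstruction code).
fuzz_read <- function(ref, pos, rng) {
  # segments: optional leading/trailing soft clips, M blocks, one optional
  # I or D in the middle
  rl_target <- 30L + rng(40L)
  lead_s <- rng(4L) - 1L
  mid <- sample(c("none", "I", "D"), 1)
  m1 <- 8L + rng(10L)
  m2 <- 8L + rng(10L)
  ilen <- if (mid == "I") rng(3L) else 0L
  dlen <- if (mid == "D") rng(3L) else 0L

  g <- pos          # reference cursor (1-based within ref)
  read <- character(0)
  qual <- character(0)
  cigar <- character(0)
  md_parts <- character(0)
  run <- 0L
  truth <- list()
  flushmd <- function() {
    md_parts <<- c(md_parts, as.character(run)); run <<- 0L
  }
  if (lead_s > 0L) {
    read <- c(read, sample(BASES, lead_s, replace = TRUE))
    cigar <- c(cigar, paste0(lead_s, "S"))
  }
  emit_m <- function(len) {
    for (i in seq_len(len)) {
      rb <- substr(ref, g, g)
      if (runif(1) < 0.15) {
        ab <- sample(setdiff(BASES, rb), 1)
        read <<- c(read, ab)
        flushmd()
        md_parts <<- c(md_parts, rb)
        truth[[length(truth) + 1L]] <<- list(gpos = g, ref = rb, alt = ab,
                                             class = "SBS")
      } else {
        read <<- c(read, rb)
        run <<- run + 1L
      }
      g <<- g + 1L
    }
    cigar <<- c(cigar, paste0(len, "M"))
  }
  emit_m(m1)
  if (mid == "I") {
    ins <- paste(sample(BASES, ilen, replace = TRUE), collapse = "")
    read <- c(read, strsplit(ins, "")[[1]])
    cigar <- c(cigar, paste0(ilen, "I"))
    truth[[length(truth) + 1L]] <- list(gpos = g - 1L, ref = "", alt = ins,
                                        class = "INS")
  } else if (mid == "D") {
    delseq <- substr(ref, g, g + dlen - 1L)
    flushmd()
    md_parts <- c(md_parts, paste0("^", delseq))
    cigar <- c(cigar, paste0(dlen, "D"))
    truth[[length(truth) + 1L]] <- list(gpos = g, ref = delseq, alt = "",
                                        class = "DEL")
    g <- g + dlen
  }
  emit_m(m2)
  flushmd()
  seq <- paste(read, collapse = "")
  list(
    pos = pos, cigar = paste(cigar, collapse = ""),
    md = paste(md_parts, collapse = ""), seq = seq,
    qual = strrep("I", nchar(seq)),
    truth = truth
  )
}

# merge adjacent substitutions of a truth list the way doublets are defined:
# runs of two adjacent SBS -> one DBS, runs of three or more discarded
merge_truth <- function(truth) {
  if (!length(truth)) {
    return(data.frame(gpos = integer(0), ref = character(0),
                      alt = character(0), class = character(0)))
  }
  df <- do.call(rbind, lapply(truth, as.data.frame))
  sbs <- df[df$class == "SBS", , drop = FALSE]
  oth <- df[df$class != "SBS", , drop = FALSE]
  out <- oth
  if (nrow(sbs)) {
    sbs <- sbs[order(sbs$gpos), , drop = FALSE]
    # genome-adjacent substitutions separated by an insertion in the read are
    # not contiguous on the read and therefore not a doublet
    ins_at <- df$gpos[df$class == "INS"]
    brk <- diff(sbs$gpos) != 1L | sbs$gpos[-nrow(sbs)] %in% ins_at
    grp <- cumsum(c(TRUE, brk))
    for (gi in unique(grp)) {
      rows <- sbs[grp == gi, , drop = FALSE]
      if (nrow(rows) == 1L) {
        out <- rbind(out, rows)
      } else if (nrow(rows) == 2L) {
        out <- rbind(out, data.frame(
          gpos = rows$gpos[1], ref = paste(rows$ref, collapse = ""),
          alt = paste(rows$alt, collapse = ""), class = "DBS"))
      } # runs >= 3: dropped
    }
  }
  out[order(out$gpos, out$class), , drop = FALSE]
}

# ---- minimal ID83 oracle ----------------------------------------------------
# Direct restatement of the indel classification rules, scanning strings.
id83_oracle <- function(type, seq, flank5, flank3) {
  L <- nchar(seq)
  nrep <- 0L
  while (substr(flank3, nrep * L + 1L, (nrep + 1L) * L) == seq) {
    nrep <- nrep + 1L
  }
  lc <- min(L, 5L)
  if (L == 1L) {
    base <- if (seq %in% c("C", "G")) "C" else "T"
    return(sprintf("1:%s:%s:%d", if (type == "DEL") "Del" else "Ins", base,
                   min(nrep, 5L)))
  }
  if (type == "INS") return(sprintf("%d:Ins:R:%d", lc, min(nrep, 5L)))
  if (nrep >= 1L) return(sprintf("%d:Del:R:%d", lc, min(nrep, 5L)))
  mh <- 0L
  for (k in 1:(L - 1L)) {
    if (substr(seq, 1L, k) == substr(flank3, 1L, k)) mh <- max(mh, k)
    if (substr(seq, L - k + 1L, L) ==
        substr(flank5, nchar(flank5) - k + 1L, nchar(flank5))) mh <- max(mh, k)
  }
  if (mh >= 1L) return(sprintf("%d:Del:M:%d", lc, min(mh, lc - 1L, 5L)))
  sprintf("%d:Del:R:0", lc)
}

# ---- shared fixtures --------------------------------------------------------
fixture_env <- new.env()

shared_fixture <- function() {
  if (is.null(fixture_env$fx)) {
    fx <- make_fixture_genome(1e6, seed = 11)
    fixture_env$fx <- fx
    fixture_env$sigs <- synthetic_signature_catalogue("SBS96")
    fixture_env$panel <- simulate_healthy_panel(fixture_env$sigs,
                                                n_samples = 60, seed = 5)
    fixture_env$thresholds <- fit_detection_thresholds(fixture_env$panel)
  }
  list(genome = fixture_env$fx$genome,
       whitelist = fixture_env$fx$whitelist,
       sigs = fixture_env$sigs,
       panel = fixture_env$panel,
       thresholds = fixture_env$thresholds)
}

# build an aligned mate pair over a genome with explicit per-mate edits
make_pair <- function(genome, start, fraglen, read_length = 100,
                      edits = list(), qname = "f1", qual_char = "I",
                      mapq = 60L) {
  gs <- genome[[1]]
  pos <- c(start, start + fraglen - read_length)
  rows <- lapply(1:2, function(m) {
    seq <- substr(gs, pos[m], pos[m] + read_length - 1L)
    qual <- strrep(qual_char, read_length)
    for (e in edits) {
      if (e$mate != m) next
      off <- e$gpos - pos[m] + 1L
      if (off < 1L || off > read_length) next
      substr(seq, off, off) <- e$alt
      if (!is.null(e$q)) {
        substr(qual, off, off) <- intToUtf8(e$q + 33L)
      }
    }
    md <- compute_md(seq, paste0(read_length, "M"),
                     substr(gs, pos[m], pos[m] + read_length - 1L))
    tibble::tibble(qname = qname, chrom = names(genome)[1], pos = pos[m],
                   mate = m, cigar = paste0(read_length, "M"), md = md,
                   seq = seq, qual = qual, mapq = mapq,
                   fraglen = fraglen, secondary = FALSE, duplicate = FALSE,
                   proper = TRUE)
  })
  dplyr::bind_rows(rows)
}
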