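# Signature catalogue container, NNLS refitting, artefact renormalisation.

#' Signature catalogues
#'
#' A signature catalogue is a channels x signatures matrix in which every
#' signature column is a probability distribution over the channels of one
#' classification scheme (SBS96, DBS78 or ID83). `signature_catalogue()`
#' validates and wraps a data frame whose first column is `channel`;
#' `read_signature_catalogue()` reads the tab-separated COSMIC layout
#' (channels as rows, signatures as columns).
#'
#' @param x Data frame with a `channel` column and one numeric column per
#'   signature.
#' @param artefacts Character vector of signature names flagged as sequencing
#'   or library-preparation artefacts (removed and renormalised away after
#'   fitting). Defaults to [default_artefact_signatures()] intersected with
#'   the available names.
#' @param scheme Channel scheme; inferred from the channel labels if omitted.
#' @return A `plasmasig_signatures` tibble with attributes `scheme` and
#'   `artefacts`.
#' @export
signature_catalogue <- function(x, artefacts = NULL, scheme = NULL) {
  x <- as_tibble(x)
  if (!"channel" %in% names(x)) {
    abort("signature_catalogue(): need a 'channel' column")
  }
  signames <- setdiff(names(x), "channel")
  if (is.null(scheme)) {
    scheme <- if (setequal(x$channel, sbs96_channels())) "SBS96"
      else if (setequal(x$channel, dbs78_channels())) "DBS78"
      else if (setequal(x$channel, id83_channels())) "ID83"
      else abort("signature_catalogue(): channels match no known scheme")
  }
  want <- switch(scheme, SBS96 = sbs96_channels(), DBS78 = dbs78_channels(),
                 ID83 = id83_channels())
  x <- x[match(want, x$channel), , drop = FALSE]
  m <- as.matrix(x[signames])
  if (any(m < 0)) abort("signature_catalogue(): negative entries")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-8)) {
    abort("signature_catalogue(): signature columns must sum to 1 (+/- 1e-8)")
  }
  if (is.null(artefacts)) {
    artefacts <- intersect(default_artefact_signatures(), signames)
  }
  structure(x, scheme = scheme, artefacts = intersect(artefacts, signames),
            class = c("plasmasig_signatures", class(x)))
}

#' @rdname signature_catalogue
#' @param path Tab-separated file, channels as rows (first column) and
#'   signatures as columns.
#' @export
read_signature_catalogue <- function(path, artefacts = NULL, scheme = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  names(tab)[1] <- "channel"
  signature_catalogue(tab, artefacts = artefacts, scheme = scheme)
}

#' @rdname signature_catalogue
#' @param sigs A `plasmasig_signatures` object.
#' @export
write_signature_catalogue <- function(sigs, path) {
  out <- as.data.frame(sigs)
  names(out)[1] <- "Type"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default artefact signature list
#'
#' The COSMIC v3.2 signatures annotated as possible sequencing artefacts
#' (SBS27, SBS43 and SBS45-SBS60); editable wherever an `artefacts` argument
#' is accepted.
#'
#' @return Character vector of signature names.
#' @export
default_artefact_signatures <- function() {
  c("SBS27", "SBS43", paste0("SBS", 45:60))
}

# deterministic "peak-like" profile: mass concentrated on a channel subset
.peaky_profile <- function(channels, peaks, peak_mass = 0.92, seed = 1) {
  withr::with_seed(seed, {
    p <- rgamma(length(channels), shape = 0.05)
    p <- p / sum(p) * (1 - peak_mass)
    pk <- rgamma(length(peaks), shape = 4)
    p[match(peaks, channels)] <- p[match(peaks, channels)] +
      pk / sum(pk) * peak_mass
    p / sum(p)
  })
}

.flat_profile <- function(channels, seed = 1, shape = 20) {
  withr::with_seed(seed, {
    p <- rgamma(length(channels), shape = shape)
    p / sum(p)
  })
}

#' Synthetic signature catalogue
#'
#' A deterministic, clearly synthetic stand-in for a COSMIC-format signature
#' matrix, for simulation studies and tests that must run without downloaded
#' reference data. Signature names follow the COSMIC naming so grouping and
#' artefact-handling code exercises realistic inputs, but the profiles are
#' generated, not measured: "peak-like" signatures (the APOBEC-like SBS2 and
#' SBS13, the UV-like SBS7a, the deamination-like SBS1) concentrate ~90% of
#' their mass on a few characteristic channels, while SBS3 and SBS5 are flat,
#' mimicking the hard-to-fit HRD profile. SBS45 and SBS52 are flagged as
#' artefacts. Real COSMIC matrices load through
#' [read_signature_catalogue()].
#'
#' @param scheme `"SBS96"`, `"DBS78"` or `"ID83"`.
#' @return A `plasmasig_signatures` object.
#' @export
synthetic_signature_catalogue <- function(scheme = c("SBS96", "DBS78",
                                                     "ID83")) {
  scheme <- match.arg(scheme)
  if (scheme == "SBS96") {
    ch <- sbs96_channels()
    prof <- list(
      SBS1  = .peaky_profile(ch, c("A[C>T]G", "C[C>T]G", "G[C>T]G",
                                   "T[C>T]G"), seed = 101),
      SBS2  = .peaky_profile(ch, c("T[C>T]A", "T[C>T]T", "T[C>T]C"),
                             seed = 102),
      SBS3  = .flat_profile(ch, seed = 103),
      SBS5  = .flat_profile(ch, seed = 105, shape = 8),
      SBS7a = .peaky_profile(ch, c("C[C>T]C", "C[C>T]T", "T[C>T]C",
                                   "T[C>T]T"), seed = 107),
      SBS13 = .peaky_profile(ch, c("T[C>G]A", "T[C>G]T", "T[C>G]C"),
                             seed = 113),
      SBS45 = .peaky_profile(ch, c("A[C>A]A", "C[C>A]A"), seed = 145),
      SBS52 = .flat_profile(ch, seed = 152, shape = 2)
    )
  } else if (scheme == "DBS78") {
    ch <- dbs78_channels()
    prof <- list(
      DBS1 = .peaky_profile(ch, c("CC>TT"), seed = 201),
      DBS2 = .peaky_profile(ch, c("CC>AA"), seed = 202),
      DBS4 = .flat_profile(ch, seed = 204),
      DBS9 = .flat_profile(ch, seed = 209, shape = 3)
    )
  } else {
    ch <- id83_channels()
    prof <- list(
      ID1 = .peaky_profile(ch, c("1:Ins:T:4", "1:Ins:T:5"), seed = 301),
      ID2 = .peaky_profile(ch, c("1:Del:T:4", "1:Del:T:5"), seed = 302),
      ID5 = .flat_profile(ch, seed = 305),
      ID6 = .peaky_profile(ch, c("5:Del:M:1", "5:Del:M:2", "5:Del:M:5"),
                           seed = 306)
    )
  }
  df <- as_tibble(c(list(channel = ch), lapply(prof, as.numeric)))
  signature_catalogue(df, scheme = scheme)
}

# Lawson-Hanson active-set non-negative least squares
.nnls <- function(A, b, tol = NULL) {
  n <- ncol(A)
  if (is.null(tol)) tol <- 1e-10 * max(abs(crossprod(A, b)), 1)
  x <- numeric(n)
  P <- logical(n)
  w <- as.numeric(crossprod(A, b - A %*% x))
  it <- 0L
  while (any(!P) && max(w[!P]) > tol && it < 30L * n) {
    it <- it + 1L
    cand <- which(!P)
    j <- cand[which.max(w[cand])]
    P[j] <- TRUE
    repeat {
      s <- numeric(n)
      s[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      s[is.na(s)] <- 0
      if (all(s[P] > tol)) { x <- s; break }
      neg <- P & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      P <- P & x > tol
      x[!P] <- 0
    }
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  list(x = x, residual = sqrt(sum((b - A %*% x)^2)))
}

#' Fit signature exposures by non-negative least squares
#'
#' Solves \eqn{\min_{e \ge 0} \| c - S e \|_2} for the raw channel count
#' vector \eqn{c} and the column-stochastic signature matrix \eqn{S}
#' (quadratic-programming refit of a fixed catalogue). Weights are the
#' exposures divided by their sum. With `drop_artefacts = TRUE` (default),
#' artefact-flagged signatures are then removed and the remaining weights
#' renormalised to sum to 1.
#'
#' @param catalogue A mutation catalogue ([build_catalogue()]) or a tibble
#'   with `channel` and `count` columns.
#' @param signatures A [signature_catalogue()].
#' @param drop_artefacts Remove artefact signatures and renormalise.
#' @param per_channel_weights `"none"` (default) or `"poisson"` for a
#'   1/sqrt(count) weighted variant.
#' @return A `plasmasig_fit` object; `tidy()` returns the per-signature
#'   weight table, `glance()` the fit summary.
#' @export
fit_signature_weights <- function(catalogue, signatures,
                                  drop_artefacts = TRUE,
                                  per_channel_weights = c("none", "poisson")) {
  per_channel_weights <- match.arg(per_channel_weights)
  stopifnot(inherits(signatures, "plasmasig_signatures"))
  cat_tbl <- as_tibble(catalogue)[, c("channel", "count")]
  sig_tbl <- as_tibble(signatures)
  if (!setequal(cat_tbl$channel, sig_tbl$channel)) {
    abort("fit_signature_weights(): catalogue and signature channels differ")
  }
  cat_tbl <- cat_tbl[match(sig_tbl$channel, cat_tbl$channel), ]
  signames <- setdiff(names(sig_tbl), "channel")
  S <- as.matrix(sig_tbl[signames])
  c_vec <- as.numeric(cat_tbl$count)
  total <- sum(c_vec)
  sample <- attr(catalogue, "sample") %||% "sample"

  if (total == 0) {
    weights <- tibble(signature = signames, exposure = 0, weight = 0,
                      artefact = signames %in% attr(signatures, "artefacts"))
    fit <- structure(list(weights = weights, residual = 0, total = 0,
                          fitted_total = 0, sample = sample,
                          scheme = attr(signatures, "scheme"),
                          no_signal = TRUE, renormalised = FALSE),
                     class = "plasmasig_fit")
    if (drop_artefacts) fit <- drop_artefacts_renormalise(fit)
    return(fit)
  }
  if (per_channel_weights == "poisson") {
    wch <- 1 / sqrt(pmax(c_vec, 1))
    sol <- .nnls(S * wch, c_vec * wch)
    sol$residual <- sqrt(sum((c_vec - S %*% sol$x)^2))
  } else {
    sol <- .nnls(S, c_vec)
  }
  e <- sol$x
  weights <- tibble(
    signature = signames,
    exposure = e,
    weight = if (sum(e) > 0) e / sum(e) else rep(0, length(e)),
    artefact = signames %in% attr(signatures, "artefacts")
  )
  fit <- structure(list(weights = weights, residual = sol$residual,
                        total = total, fitted_total = sum(e),
                        sample = sample, scheme = attr(signatures, "scheme"),
                        no_signal = sum(e) == 0, renormalised = FALSE),
                   class = "plasmasig_fit")
  if (drop_artefacts) fit <- drop_artefacts_renormalise(fit)
  fit
}

#' Remove artefact signatures and renormalise the weights
#'
#' Sets artefact-flagged signatures absent and divides the remaining weights
#' by their sum, so that each sample's weights sum to exactly 1 whenever any
#' non-artefact weight is positive. If nothing remains the sample is flagged
#' `no_signal` with all weights zero.
#'
#' @param fit A `plasmasig_fit`.
#' @param artefacts Optional replacement artefact name list.
#' @return The updated `plasmasig_fit`.
#' @export
drop_artefacts_renormalise <- function(fit, artefacts = NULL) {
  stopifnot(inherits(fit, "plasmasig_fit"))
  w <- fit$weights
  if (!is.null(artefacts)) w$artefact <- w$signature %in% artefacts
  keep <- w[!w$artefact, , drop = FALSE]
  s <- sum(keep$weight)
  if (s > 0) {
    keep$weight <- keep$weight / s
  } else {
    keep$weight <- 0
    fit$no_signal <- TRUE
  }
  fit$weights <- keep
  fit$renormalised <- TRUE
  fit
}

#' @export
print.plasmasig_fit <- function(x, ...) {
  top <- x$weights %>% arrange(dplyr::desc(.data$weight)) %>% head(5)
  cat(sprintf("<plasmasig signature fit: %s (%s), %g mutations%s>\n",
              x$sample, x$scheme, x$total,
              if (x$no_signal) ", no signal" else ""))
  for (i in seq_len(nrow(top))) {
    if (top$weight[i] > 0) {
      cat(sprintf("  %-8s %.3f\n", top$signature[i], top$weight[i]))
    }
  }
  invisible(x)
}

#' @export
#' @method tidy plasmasig_fit
tidy.plasmasig_fit <- function(x, ...) {
  mutate(x$weights, sample = x$sample, .before = 1)
}

#' @export
#' @method glance plasmasig_fit
glance.plasmasig_fit <- function(x, ...) {
  tibble(sample = x$sample, scheme = x$scheme, total_mutations = x$total,
         fitted_total = x$fitted_total, residual = x$residual,
         n_active = sum(x$weights$weight > 0), no_signal = x$no_signal,
         renormalised = x$renormalised)
}

#' Cosine similarity between signature weight vectors
#'
#' Standard cosine similarity; defined as 0 when either vector has zero norm.
#' With named vectors and a `subset`, both vectors are restricted to the same
#' ordered signature subset first.
#'
#' @param a,b Numeric vectors (optionally named by signature).
#' @param subset Optional character vector of signature names.
#' @return A number in `[0, 1]` (for non-negative inputs).
#' @export
cosine_similarity <- function(a, b, subset = NULL) {
  if (!is.null(subset)) {
    a <- a[subset]
    b <- b[subset]
    a[is.na(a)] <- 0
    b[is.na(b)] <- 0
  }
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Group signature weights into process-level categories
#'
#' Sums the weights of related signatures (e.g. the APOBEC pair SBS2/SBS13)
#' into named groups; signatures not covered by the grouping pass through
#' unchanged. Groups must not overlap.
#'
#' @param weights Tibble with `signature` and `weight` columns (e.g.
#'   `tidy(fit)`).
#' @param groups Named list of character vectors, e.g.
#'   `list(APOBEC = c("SBS2", "SBS13"))`.
#' @return Tibble with `signature` (group or original name) and `weight`.
#' @export
group_signatures <- function(weights, groups = list()) {
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members)) {
    abort("group_signatures(): groups overlap")
  }
  grouped <- purrr::imap_dfr(groups, function(sigs, nm) {
    tibble(signature = nm,
           weight = sum(weights$weight[weights$signature %in% sigs]))
  })
  rest <- weights[!weights$signature %in% members, c("signature", "weight")]
  bind_rows(grouped, rest)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
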