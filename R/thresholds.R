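# Per-signature detection thresholds from a panel of healthy plasma controls.

#' Trim the extreme samples from a panel weight vector
#'
#' Removes exactly one maximum and one minimum value (the two most extreme
#' samples), for a more conservative beta fit; ties are broken by first
#' occurrence.
#'
#' @param x Numeric vector of one signature's weights across panel samples
#'   (length >= 4).
#' @param n_trim Values removed from each end (default 1; set 2 to drop the
#'   two highest and two lowest samples).
#' @return The trimmed vector.
#' @export
trim_panel <- function(x, n_trim = 1L) {
  if (length(x) < 2L * n_trim + 2L) {
    abort(sprintf(
      "trim_panel(): need at least %d panel samples, got %d",
      2L * n_trim + 2L, length(x)), class = "plasmasig_panel_too_small")
  }
  for (i in seq_len(n_trim)) {
    x <- x[-which.max(x)]
    x <- x[-which.min(x)]
  }
  x
}

#' Closed-form beta fit by moment matching
#'
#' Matches the beta distribution's mean and variance to the sample moments:
#' with mean \eqn{m} and variance \eqn{v},
#' \eqn{\alpha = m (m(1-m)/v - 1)} and \eqn{\beta = (1-m)(m(1-m)/v - 1)}.
#' Values are clamped into `[1e-6, 1 - 1e-6]` first, since exact zeros are
#' common in signature weight tables and the beta moments are undefined at
#' the boundary. When the variance reaches or exceeds \eqn{m(1-m)} (or is
#' zero) the fit is flagged degenerate. With `refine = TRUE` the
#' moment-matching estimate seeds a numerical maximum-likelihood refinement.
#'
#' @param x Numeric weights in `[0, 1]`.
#' @param refine Refine the closed-form estimate by maximum likelihood.
#' @return A list with `alpha`, `beta`, `degenerate`, `mean`, `var`.
#' @export
fit_beta_mme <- function(x, refine = FALSE) {
  x <- pmin(pmax(x, 1e-6), 1 - 1e-6)
  m <- mean(x)
  v <- var(x)
  if (!is.finite(v) || v <= 0 || v >= m * (1 - m)) {
    return(list(alpha = NA_real_, beta = NA_real_, degenerate = TRUE,
                mean = m, var = v))
  }
  k <- m * (1 - m) / v - 1
  a <- m * k
  b <- (1 - m) * k
  if (refine) {
    nll <- function(p) -sum(dbeta(x, exp(p[1]), exp(p[2]), log = TRUE))
    opt <- tryCatch(optim(log(c(a, b)), nll), error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value)) {
      a <- exp(opt$par[1])
      b <- exp(opt$par[2])
    }
  }
  list(alpha = a, beta = b, degenerate = FALSE, mean = m, var = v)
}

#' 99th-percentile detection threshold of a fitted beta
#'
#' The inverse regularised incomplete beta function at 0.99.
#'
#' @param alpha,beta Beta shape parameters (> 0).
#' @param q Quantile level (default 0.99).
#' @return The threshold in `(0, 1)`.
#' @export
threshold_q99 <- function(alpha, beta, q = 0.99) {
  stopifnot(is.finite(alpha), is.finite(beta), alpha > 0, beta > 0)
  qbeta(q, alpha, beta)
}

#' Fit per-signature detection thresholds from a healthy panel
#'
#' For each signature, the panel weights are trimmed of their extreme
#' samples, a beta distribution is fitted by moment matching and its 99th
#' quantile becomes the detection threshold. Degenerate fits (zero or
#' moment-incompatible variance) fall back to the empirical maximum of the
#' trimmed panel plus a small floor.
#'
#' @param panel Long tibble with columns `sample`, `signature`, `weight`
#'   (one row per panel sample and signature), e.g. from
#'   [simulate_healthy_panel()] or a stack of `tidy()` fit results.
#' @param q Quantile level for the threshold (default 0.99).
#' @param n_trim Samples trimmed from each end per signature (default 1).
#' @param refine Numerical ML refinement of the beta fit (default off).
#' @param degenerate_floor Margin added to the empirical maximum for
#'   degenerate fits (default 0.01).
#' @return A `plasmasig_thresholds` object; `tidy()` returns the per-signature
#'   table (`signature`, `alpha`, `beta`, `threshold`, `n`, `degenerate`).
#' @export
fit_detection_thresholds <- function(panel, q = 0.99, n_trim = 1L,
                                     refine = FALSE,
                                     degenerate_floor = 0.01) {
  stopifnot(all(c("sample", "signature", "weight") %in% names(panel)))
  tab <- panel %>%
    group_by(.data$signature) %>%
    summarise(fit = list({
      w <- trim_panel(.data$weight, n_trim = n_trim)
      f <- fit_beta_mme(w, refine = refine)
      thr <- if (f$degenerate) min(max(w) + degenerate_floor, 1) else {
        threshold_q99(f$alpha, f$beta, q = q)
      }
      tibble(alpha = f$alpha, beta = f$beta, threshold = thr,
             n = length(w), degenerate = f$degenerate)
    }), .groups = "drop") %>%
    tidyr::unnest("fit")
  structure(list(thresholds = tab, q = q, n_trim = n_trim,
                 n_samples = n_distinct(panel$sample)),
            class = "plasmasig_thresholds")
}

#' @export
print.plasmasig_thresholds <- function(x, ...) {
  cat(sprintf(
    "<plasmasig detection thresholds: %d signatures, %d panel samples, q = %.2f>\n",
    nrow(x$thresholds), x$n_samples, x$q))
  print(x$thresholds, n = 10)
  invisible(x)
}

#' @export
#' @method tidy plasmasig_thresholds
tidy.plasmasig_thresholds <- function(x, ...) x$thresholds

#' @export
#' @method glance plasmasig_thresholds
glance.plasmasig_thresholds <- function(x, ...) {
  tibble(n_signatures = nrow(x$thresholds), n_samples = x$n_samples,
         q = x$q, n_trim = x$n_trim,
         n_degenerate = sum(x$thresholds$degenerate))
}

#' Call signatures over-represented relative to the healthy panel
#'
#' A signature is detected when its weight strictly exceeds its panel-derived
#' threshold (the threshold itself is the 99th quantile of "healthy", so
#' equality is non-evidence).
#'
#' @param weights Tibble with `signature` and `weight` columns (e.g.
#'   `tidy(fit)`).
#' @param thresholds A `plasmasig_thresholds` object (or its `tidy()` table).
#' @return Tibble with `signature`, `weight`, `threshold`, `margin`
#'   (`weight - threshold`) and `detected`.
#' @export
call_detected <- function(weights, thresholds) {
  thr <- if (inherits(thresholds, "plasmasig_thresholds")) {
    thresholds$thresholds
  } else thresholds
  missing <- setdiff(weights$signature, thr$signature)
  if (length(missing)) {
    abort(sprintf("call_detected(): no threshold fitted for: %s",
                  paste(missing, collapse = ", ")),
          class = "plasmasig_missing_threshold")
  }
  weights %>%
    select("signature", "weight") %>%
    left_join(select(thr, "signature", "threshold"), by = "signature") %>%
    mutate(margin = .data$weight - .data$threshold,
           detected = .data$weight > .data$threshold)
}

#' Simulate a healthy-control signature weight panel
#'
#' Draws per-sample signature weights from a Dirichlet model: healthy plasma
#' is dominated by clock-like/flat background processes with small,
#' fluctuating contributions from the remaining signatures — the situation in
#' which per-signature beta detection thresholds are fitted in practice.
#' Weights are Dirichlet-distributed, so each signature's marginal is a beta
#' distribution and the panel matches the threshold model by construction.
#'
#' @param signatures Character vector of signature names, or a
#'   [signature_catalogue()] whose names are used.
#' @param n_samples Panel size (default 60).
#' @param concentration Named numeric vector of Dirichlet concentrations; any
#'   signature not named gets `base_concentration`. The default puts most
#'   mass on SBS1/SBS5-like background when present.
#' @param base_concentration Concentration for unnamed signatures
#'   (default 0.4).
#' @param seed Mandatory seed.
#' @return Long tibble `sample`, `signature`, `weight` (weights per sample
#'   sum to 1).
#' @export
simulate_healthy_panel <- function(signatures, n_samples = 60,
                                   concentration = NULL,
                                   base_concentration = 0.4, seed) {
  if (inherits(signatures, "plasmasig_signatures")) {
    signatures <- setdiff(names(signatures), "channel")
  }
  conc <- rep(base_concentration, length(signatures))
  names(conc) <- signatures
  if (is.null(concentration)) {
    concentration <- c(SBS1 = 4, SBS5 = 10, ID5 = 6, DBS4 = 6)
  }
  hit <- intersect(names(concentration), signatures)
  conc[hit] <- concentration[hit]
  withr::with_seed(seed, {
    g <- matrix(rgamma(n_samples * length(conc), shape = rep(conc,
                                                             each = n_samples)),
                nrow = n_samples)
    w <- g / rowSums(g)
  })
  colnames(w) <- signatures
  as_tibble(w) %>%
    mutate(sample = sprintf("healthy%03d", seq_len(n_samples))) %>%
    tidyr::pivot_longer(-"sample", names_to = "signature",
                        values_to = "weight")
}
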