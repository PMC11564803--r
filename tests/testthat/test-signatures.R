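sigs_t <- synthetic_signature_catalogue("SBS96")
S_t <- as.matrix(sigs_t[setdiff(names(sigs_t), "channel")])

test_that("signature catalogue container validates its invariants", {
  expect_equal(attr(sigs_t, "scheme"), "SBS96")
  expect_true(all(abs(colSums(S_t) - 1) < 1e-8))
  expect_setequal(attr(sigs_t, "artefacts"), c("SBS45", "SBS52"))
  bad <- as.data.frame(sigs_t)
  bad$SBS1 <- bad$SBS1 * 2
  expect_error(signature_catalogue(bad), "sum to 1")
})

test_that("NNLS refit recovers exact mixtures and matches an active-set oracle", {
  c_exact <- as.numeric(10000 * (0.6 * S_t[, "SBS2"] + 0.4 * S_t[, "SBS7a"]))
  fit <- fit_signature_weights(
    as_catalogue(setNames(c_exact, sigs_t$channel), "SBS96"), sigs_t,
    drop_artefacts = FALSE)
  w <- setNames(fit$weights$weight, fit$weights$signature)
  expect_lt(abs(w[["SBS2"]] - 0.6), 1e-6)
  expect_lt(abs(w[["SBS7a"]] - 0.4), 1e-6)
  expect_lt(sum(w[setdiff(names(w), c("SBS2", "SBS7a"))]), 1e-6)
  # independent active-set solver on the same inputs
  skip_if_not_installed("pracma")
  e_oracle <- pracma::lsqnonneg(S_t, c_exact)$x
  expect_equal(fit$weights$exposure, e_oracle, tolerance = 1e-8)
})

test_that("a catalogue equal to one signature column fits weight 1 on it", {
  c1 <- as.numeric(5000 * S_t[, "SBS13"])
  fit <- fit_signature_weights(
    as_catalogue(setNames(c1, sigs_t$channel), "SBS96"), sigs_t,
    drop_artefacts = FALSE)
  expect_equal(fit$weights$weight[fit$weights$signature == "SBS13"], 1,
               tolerance = 1e-9)
})

test_that("fit is symmetric under column permutation and invariant to scale", {
  c0 <- as.numeric(1000 * (0.3 * S_t[, "SBS1"] + 0.7 * S_t[, "SBS3"]))
  cat0 <- as_catalogue(setNames(c0, sigs_t$channel), "SBS96")
  perm <- sigs_t[, c("channel", sample(setdiff(names(sigs_t), "channel")))]
  perm <- signature_catalogue(as.data.frame(perm), artefacts = character(0))
  f1 <- fit_signature_weights(cat0, sigs_t, drop_artefacts = FALSE)
  f2 <- fit_signature_weights(cat0, perm, drop_artefacts = FALSE)
  w1 <- setNames(f1$weights$weight, f1$weights$signature)
  w2 <- setNames(f2$weights$weight, f2$weights$signature)
  expect_equal(w1[sort(names(w1))], w2[sort(names(w2))], tolerance = 1e-9)
  # scale invariance
  f3 <- fit_signature_weights(
    as_catalogue(setNames(17 * c0, sigs_t$channel), "SBS96"), sigs_t,
    drop_artefacts = FALSE)
  expect_equal(f3$weights$weight, f1$weights$weight, tolerance = 1e-9)
})

test_that("multinomial-sampled mixtures are recovered with small L1 error", {
  truth <- c(SBS2 = 0.55, SBS7a = 0.45)
  p <- as.numeric(S_t %*% ifelse(colnames(S_t) %in% names(truth),
                                 truth[colnames(S_t)], 0))
  p[is.na(p)] <- 0
  l1 <- vapply(1:20, function(s) {
    set.seed(s)
    counts <- as.numeric(rmultinom(1, 1e4, p))
    fit <- fit_signature_weights(
      as_catalogue(setNames(counts, sigs_t$channel), "SBS96"), sigs_t,
      drop_artefacts = FALSE)
    w <- setNames(fit$weights$weight, fit$weights$signature)
    sum(abs(w[names(truth)] - truth)) +
      sum(w[setdiff(names(w), names(truth))])
  }, numeric(1))
  expect_lt(mean(l1), 0.05)
})

test_that("fitted exposures satisfy the non-negative least-squares optimality conditions", {
  set.seed(77)
  for (i in 1:5) {
    b <- as.numeric(rmultinom(1, 2000, as.numeric(S_t %*% runif(ncol(S_t)))))
    fit <- fit_signature_weights(
      as_catalogue(setNames(b, sigs_t$channel), "SBS96"), sigs_t,
      drop_artefacts = FALSE)
    e <- fit$weights$exposure
    g <- as.numeric(crossprod(S_t, S_t %*% e - b))
    active <- e > 1e-8
    expect_true(all(abs(g[active]) < 1e-6 * max(1, max(abs(g)))))
    expect_true(all(g[!active] > -1e-6 * max(1, max(abs(g)))))
    # perturbing any exposure never reduces the residual
    r0 <- sum((b - S_t %*% e)^2)
    for (j in seq_along(e)) {
      for (eps in c(1e-4, -1e-4)) {
        e2 <- e
        e2[j] <- max(0, e2[j] + eps)
        expect_gte(sum((b - S_t %*% e2)^2), r0 - 1e-9)
      }
    }
  }
})

test_that("all-zero catalogues give a defined no-signal result", {
  fit <- fit_signature_weights(
    as_catalogue(setNames(rep(0, 96), sigs_t$channel), "SBS96"), sigs_t)
  expect_true(fit$no_signal)
  expect_true(all(fit$weights$weight == 0))
})

test_that("artefact removal renormalises the remaining weights to one", {
  fit <- fit_signature_weights(
    as_catalogue(setNames(as.numeric(1000 * S_t[, "SBS2"]), sigs_t$channel),
                 "SBS96"), sigs_t, drop_artefacts = FALSE)
  # force a known weight layout
  fit$weights$weight <- c(0.5, 0.3, 0.2, rep(0, nrow(fit$weights) - 3))
  fit$weights$artefact <- c(TRUE, rep(FALSE, nrow(fit$weights) - 1))
  out <- drop_artefacts_renormalise(fit)
  expect_equal(out$weights$weight[1:2], c(0.6, 0.4))
  expect_equal(sum(out$weights$weight), 1, tolerance = 1e-12)
  expect_false(any(out$weights$artefact))
  # no artefacts flagged: weights unchanged
  fit2 <- fit_signature_weights(
    as_catalogue(setNames(as.numeric(1000 * S_t[, "SBS2"]), sigs_t$channel),
                 "SBS96"),
    signature_catalogue(as.data.frame(sigs_t), artefacts = character(0)),
    drop_artefacts = FALSE)
  out2 <- drop_artefacts_renormalise(fit2)
  expect_equal(out2$weights$weight, fit2$weights$weight)
})

test_that("cosine similarity handles the degenerate and hand-computed cases", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(cosine_similarity(c(0, 0), c(1, 1)), 0)
  a <- c(SBS1 = 0.2, SBS2 = 0.8)
  b <- c(SBS2 = 0.8, SBS3 = 0.2)
  expect_equal(cosine_similarity(a, b, subset = c("SBS2")), 1)
})

test_that("signature grouping sums members, preserves the rest, rejects overlap", {
  w <- tibble::tibble(signature = c("SBS2", "SBS13", "SBS5"),
                      weight = c(0.2, 0.1, 0.7))
  g <- group_signatures(w, list(APOBEC = c("SBS2", "SBS13")))
  expect_equal(g$weight[g$signature == "APOBEC"], 0.3)
  expect_equal(g$weight[g$signature == "SBS5"], 0.7)
  expect_equal(sum(g$weight), sum(w$weight))
  expect_equal(group_signatures(w, list()), w[, c("signature", "weight")])
  expect_error(group_signatures(w, list(A = "SBS2", B = c("SBS2", "SBS5"))),
               "overlap")
})
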