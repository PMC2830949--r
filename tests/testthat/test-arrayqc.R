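make_ref_pair <- function(n = 5000, seed = 1L, transform = function(r) r) {
  withr::with_seed(seed, {
    ref <- rlnorm(n, log(500), 0.8)
    vals <- cbind(REF = ref, S = transform(ref))
    rownames(vals) <- sprintf("P%05d", seq_len(n))
    expression_matrix(vals, c(REF = "control", S = "control"))
  })
}

test_that("rank-invariant normalisation recovers a pure scaling", {
  x <- make_ref_pair(transform = function(r) r * 2)
  norm <- rank_invariant_normalize(x, "REF")
  expect_equal(unname(attr(norm, "scale_factors")["S"]), 0.5, tolerance = 1e-12)
  expect_equal(norm$values[, "S"], norm$values[, "REF"], tolerance = 1e-12)
  expect_identical(norm$values[, "REF"], x$values[, "REF"])  # reference untouched
})

test_that("rank-invariant normalisation is the identity on identical samples", {
  x <- make_ref_pair(transform = identity)
  norm <- rank_invariant_normalize(x, "REF")
  expect_equal(norm$values, x$values, tolerance = 1e-12)
})

test_that("perturbed probes are excluded from the invariant set", {
  x <- make_ref_pair(seed = 3L, transform = function(r) {
    s <- r * 2
    idx <- seq_len(length(r) * 0.05)   # 5% of probes blown up 10-fold
    s[idx] <- s[idx] * 10
    s
  })
  norm <- rank_invariant_normalize(x, "REF")
  f <- unname(attr(norm, "scale_factors")["S"])
  expect_lt(abs(f / 0.5 - 1), 0.01)
  inv <- attr(norm, "invariant_sets")[["S"]]
  # nearly all perturbed probes drop out (a handful at the extreme ranks may
  # survive, where a 10-fold shift barely moves the rank)
  expect_lt(sum(sprintf("P%05d", 1:250) %in% inv), 25)
  # brute-force recomputation of the trimmed-mean ratio over the invariant set
  f_oracle <- mean(x$values[inv, "REF"], trim = 0.1) / mean(x$values[inv, "S"], trim = 0.1)
  expect_equal(f, f_oracle, tolerance = 1e-12)
})

test_that("normalisation errors when the invariant set collapses", {
  withr::with_seed(5L, {
    vals <- cbind(REF = rlnorm(300, log(100), 0.5), S = rlnorm(300, log(100), 0.5))
    rownames(vals) <- sprintf("P%03d", 1:300)
    x <- expression_matrix(vals, c(REF = "control", S = "control"))
  })
  expect_error(rank_invariant_normalize(x, "REF", rank_tol = 0.001, min_set = 250),
               "normalisation error")
  expect_error(rank_invariant_normalize(x, "NOPE"), "not in matrix")
})

test_that("detection score is the tie-aware exceedance over negative controls", {
  neg_vals <- matrix(as.numeric(1:100), ncol = 1, dimnames = list(sprintf("N%03d", 1:100), "S"))
  neg <- expression_matrix(neg_vals, c(S = "control"))
  gv <- matrix(c(1000, 0.5, 50), ncol = 1, dimnames = list(c("above", "below", "mid"), "S"))
  x <- expression_matrix(gv, c(S = "control"))
  d <- detection_scores(x, neg)
  expect_equal(unname(d["above", "S"]), 1)      # exceeds every control
  expect_equal(unname(d["below", "S"]), 0)      # below every control
  # equal to the 50th of 100 distinct controls: 49 below + half a tie
  expect_equal(unname(d["mid", "S"]), 0.495, tolerance = 1e-12)
  expect_identical(attr(d, "n_neg"), 100L)
  small <- expression_matrix(neg_vals[1:10, , drop = FALSE], c(S = "control"))
  expect_error(detection_scores(x, small), "at least 20")
})

test_that("diff score matches its signed log-p definition and an erf oracle", {
  # negative controls engineered so the variance model is known
  neg_vals <- matrix(rep(c(90, 110), 50), ncol = 2,
                     dimnames = list(sprintf("N%03d", 1:50), c("A", "B")))
  neg <- expression_matrix(neg_vals, c(A = "control", B = "control"))
  vm <- fit_variance_model(neg, cv = 0)
  sigma0 <- vm$sigma0
  expect_equal(diff_score(500, 500, vm), 0)                    # no difference
  # difference placed exactly at the two-sided p = 1e-5 z quantile: DS = 50
  z_at_50 <- -qnorm(5e-6)
  d <- z_at_50 * sqrt(2 * sigma0^2)
  expect_equal(diff_score(500 + d, 500, vm), 50, tolerance = 1e-9)
  expect_equal(diff_score(500, 500 + d, vm), -50, tolerance = 1e-9)
  # independent oracle: p from the complementary error function
  skip_if_not_installed("pracma")
  vm2 <- fit_variance_model(neg, cv = 0.1)
  xp <- 700; xc <- 400
  z <- (xp - xc) / sqrt(vm2$v(xp) + vm2$v(xc))
  expect_equal(diff_score(xp, xc, vm2), -10 * log10(pracma::erfc(abs(z) / sqrt(2))),
               tolerance = 1e-9)
  expect_error(diff_score(-1, 5, vm), "positive intensities")
})

# a handmade discovery design: 1 patient, 3 controls, tiny technical noise
manual_discovery <- function(patient_vals, control_vals, sigma0 = 1) {
  genes <- names(patient_vals)
  vals <- cbind(P = patient_vals,
                C1 = vapply(control_vals, `[`, numeric(1), 1),
                C2 = vapply(control_vals, `[`, numeric(1), 2),
                C3 = vapply(control_vals, `[`, numeric(1), 3))
  rownames(vals) <- genes
  x <- expression_matrix(vals, c(P = "truncating", C1 = "control",
                                 C2 = "control", C3 = "control"))
  neg_vals <- matrix(rep(c(10 - sigma0, 10 + sigma0), 200), nrow = 100, ncol = 4,
                     dimnames = list(sprintf("N%03d", 1:100), colnames(vals)))
  neg <- expression_matrix(neg_vals, x$groups)
  det <- detection_scores(x, neg)
  list(x = x, det = det, vm = fit_variance_model(neg, cv = 0.001))
}

test_that("genes under twofold are excluded however strong their score", {
  d <- manual_discovery(c(g1 = 1900), list(g1 = c(1000, 1000, 1000)))
  # DS is enormous with this variance model, but fold 1.9 < 2
  expect_gt(abs(diff_score(1900, 1000, d$vm)), 200)
  cand <- select_candidates(d$x, d$det, "P", c("C1", "C2", "C3"),
                            candidate_thresholds(), d$vm)
  expect_equal(nrow(cand), 0)
})

test_that("consistent up/down spikes reach the standard or strict tier", {
  d <- manual_discovery(c(up = 3000, down = 250, flat = 1000),
                        list(up = c(1000, 990, 1010),
                             down = c(1000, 990, 1010),
                             flat = c(1000, 990, 1010)))
  cand <- select_candidates(d$x, d$det, "P", c("C1", "C2", "C3"),
                            candidate_thresholds(), d$vm)
  expect_setequal(cand$gene_id, c("up", "down"))
  expect_true(all(cand$tier == "strict"))
  expect_true(all(cand$n_consistent == 3))
  expect_gt(cand$min_fold[cand$gene_id == "down"], 2)  # reciprocal fold
  # strict-tier genes also satisfy the standard tier's DS and fold bounds
  expect_true(all(cand$min_ds[cand$tier == "strict"] > 50))
  expect_true(all(cand$min_fold > 2))
})

test_that("a gene passing two of three controls lands in the relaxed tier", {
  d <- manual_discovery(c(g1 = 4000), list(g1 = c(1000, 1000, 3900)))
  cand <- select_candidates(d$x, d$det, "P", c("C1", "C2", "C3"),
                            candidate_thresholds(), d$vm)
  expect_equal(cand$tier, "relaxed")
  expect_equal(cand$n_consistent, 2)
})

test_that("selection is invariant under global rescaling of the dataset", {
  cfg <- sim_config(n_genes = 2000, n_neg_controls = 500,
                    spike_table = data.frame(gene_id = sprintf("S%02d", 1:5),
                                             group = "truncating", fold = 5),
                    group_sizes = c(truncating = 1L, control = 3L),
                    cv_within = 0.1, seed = 91L)
  arr <- simulate_array_experiment(cfg)
  run_selection <- function(expr, neg) {
    controls <- names(expr$groups)[expr$groups == "control"]
    norm <- rank_invariant_normalize(expr, controls[1])
    det <- detection_scores(norm, neg)
    select_candidates(norm, det, "PT01", controls,
                      candidate_thresholds(), fit_variance_model(neg, cv = 0.1))
  }
  a <- run_selection(arr$expr, arr$neg_controls)
  scaled <- expression_matrix(arr$expr$values * 7.3, arr$expr$groups)
  neg_scaled <- expression_matrix(arr$neg_controls$values * 7.3, arr$neg_controls$groups)
  b <- run_selection(scaled, neg_scaled)
  expect_identical(a$gene_id, b$gene_id)
  expect_identical(a$tier, b$tier)
  expect_equal(a$min_ds, b$min_ds, tolerance = 1e-9)
})

test_that("null discovery simulations yield essentially no strict-tier calls", {
  strict_total <- 0L
  for (i in 1:20) {
    cfg <- sim_config(n_genes = 10000, n_neg_controls = 1000,
                      group_sizes = c(truncating = 1L, control = 3L),
                      cv_within = 0.1, seed = 2000L + i)
    arr <- simulate_array_experiment(cfg)
    controls <- c("C01", "C02", "C03")
    norm <- rank_invariant_normalize(arr$expr, "C01")
    det <- detection_scores(norm, arr$neg_controls)
    cand <- select_candidates(norm, det, "PT01", controls,
                              candidate_thresholds(),
                              fit_variance_model(arr$neg_controls, cv = 0.1))
    strict_total <- strict_total + sum(cand$tier == "strict")
  }
  expect_lte(strict_total, 2)
})

test_that("threshold configuration rejects non-positive bounds", {
  expect_error(candidate_thresholds(ds = -1), "configuration error")
  expect_error(candidate_thresholds(min_fold = 0), "configuration error")
})
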