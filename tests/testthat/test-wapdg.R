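two_group_matrix <- function(vals_by_gene, groups) {
  vals <- do.call(rbind, vals_by_gene)
  rownames(vals) <- names(vals_by_gene)
  colnames(vals) <- names(groups)
  expression_matrix(vals, groups)
}

test_that("grand-mean weighting yields unit-mean, scale-free gene profiles", {
  groups <- c(s1 = "missense", s2 = "missense", s3 = "control", s4 = "control")
  x <- two_group_matrix(list(const = c(5, 5, 5, 5),
                             var = c(2, 6, 2, 6)), groups)
  w <- weight_expression(x)
  expect_equal(unname(w$values["const", ]), rep(1, 4))          # self-normalising
  expect_equal(unname(rowMeans(w$values)), c(1, 1))             # unit grand mean
  doubled <- expression_matrix(x$values * 2, groups)
  expect_equal(weight_expression(doubled)$values, w$values)     # scale invariance
  # hand computation: {2, 6} has grand mean 4 -> weights {0.5, 1.5}
  pair <- two_group_matrix(list(g = c(2, 6)),
                           c(a = "missense", b = "control"))
  expect_equal(unname(weight_expression(pair)$values["g", ]), c(0.5, 1.5))
  zero <- two_group_matrix(list(g = c(0, 0)), c(a = "missense", b = "control"))
  expect_error(weight_expression(zero), "grand mean")
})

test_that("group summaries are the per-group sample means and SDs", {
  groups <- c(s1 = "missense", s2 = "missense", s3 = "control",
              s4 = "control", s5 = "control")
  x <- two_group_matrix(list(g1 = c(0.5, 1.5, 1, 1, 1)), groups)
  s <- summarize_groups(weight_expression(x))
  mis <- s[s$group == "missense", ]
  ctl <- s[s$group == "control", ]
  expect_equal(mis$mean, 1)
  expect_equal(mis$sd, sqrt(0.5), tolerance = 1e-12)   # sd of {0.5, 1.5}
  expect_equal(ctl$mean, 1)
  expect_equal(ctl$sd, 0)
  # pooling both groups conserves the weighting invariant (overall mean 1)
  expect_equal(sum(s$mean * s$n) / sum(unique(s$n)), 1, tolerance = 1e-12)
  lone <- two_group_matrix(list(g1 = c(1, 2, 3)),
                           c(s1 = "missense", s2 = "control", s3 = "control"))
  expect_error(summarize_groups(weight_expression(lone)), "size 1")
})

test_that("permutation draws respect the truncated-normal model", {
  summ <- data.frame(gene_id = "g", group = c("degenerate", "narrow", "truncated"),
                     mean = c(1, 3, 0.5), sd = c(0, 0.1, 1), n = 5)
  expect_identical(withr::with_seed(1L, permute_group(summ, "g", "degenerate", 1000)),
                   rep(1, 1000))
  narrow <- withr::with_seed(2L, permute_group(summ, "g", "narrow", 4000))
  expect_lt(abs(mean(narrow) - 3), 4 * 0.1 / sqrt(4000))  # truncation inactive
  expect_lt(abs(sample_skewness(narrow)), 0.15)
  trunc <- withr::with_seed(3L, permute_group(summ, "g", "truncated", 4000))
  expect_true(all(trunc > 0))
  expect_gt(mean(trunc), 0.5)
  expect_gt(sample_skewness(trunc), 0.2)  # the slight positive skew
  # closed-form truncated-normal mean: mu + sd * phi(-mu/sd) / Phi(mu/sd)
  m_theory <- 0.5 + 1 * dnorm(-0.5) / pnorm(0.5)
  expect_lt(abs(mean(trunc) - m_theory), 0.06)
  bad <- data.frame(gene_id = "g", group = "impossible", mean = -1, sd = 0, n = 5)
  expect_error(permute_group(bad, "g", "impossible", 10), "no positive support")
})

test_that("shared proportion matches an exhaustive-count oracle", {
  expect_equal(shared_proportion(c(1, 2, 3), c(1, 2, 3)), 1)          # identical
  expect_equal(shared_proportion(c(0.1, 0.9), c(2.1, 2.9)), 0)        # disjoint
  expect_equal(shared_proportion(c(1, 2, 3), c(2.5, 3.5)), 0.4)       # worked case
  withr::with_seed(37L, {
    for (i in 1:50) {
      a <- round(runif(sample(1:10, 1), 0, 4), 2)
      b <- round(runif(sample(1:10, 1), 1, 5), 2)
      expect_equal(shared_proportion(a, b), shared_proportion_oracle(a, b))
    }
  })
  expect_error(shared_proportion(numeric(0), 1), "non-empty")
})

test_that("combining genes averages independent draws and sharpens separation", {
  summ <- rbind(
    data.frame(gene_id = paste0("g", 1:6), group = "patient", mean = 1.4, sd = 0.35, n = 12),
    data.frame(gene_id = paste0("g", 1:6), group = "control", mean = 0.8, sd = 0.25, n = 5))
  perms <- build_permutation_set(summ, n_draws = 1000, seed = 41L)
  one <- combine_genes(perms, "g1")
  expect_identical(one$patient, perms$draws$g1$patient)   # size-1 panel: identity
  # oracle: an independent mean-of-draws reimplementation
  panel <- paste0("g", 1:4)
  comb <- combine_genes(perms, panel)
  oracle <- sapply(seq_len(1000), function(i) {
    mean(vapply(panel, function(g) perms$draws[[g]][["patient"]][i], numeric(1)))
  })
  expect_equal(comb$patient, oracle, tolerance = 1e-12)
  # overlap shrinks as the panel grows (1/G variance shrinkage)
  overlaps <- vapply(c(1, 3, 6), function(G) {
    cg <- combine_genes(perms, paste0("g", 1:G))
    shared_proportion(cg$patient, cg$control)
  }, numeric(1))
  expect_true(all(diff(overlaps) <= 0))
  expect_lt(overlaps[3], overlaps[1])
  # opposing directions must be inverted before combination
  dirs <- c(g1 = 1, g2 = -1)
  expect_error(combine_genes(perms, c("g1", "g2"), directions = dirs),
               "mixing up- and down-regulated")
})

test_that("wapdg_analyze is deterministic and respects its resolution floor", {
  mat <- make_quantity_matrix(paste0("g", 1:5),
                              c(missense = 8L, truncating = 4L, control = 5L),
                              data.frame(gene_id = paste0("g", 1:5),
                                         group = "missense", fold = 3),
                              cv = 0.25, seed = 43L)
  r1 <- wapdg_analyze(mat, n_draws = 500, seed = 99L)
  r2 <- wapdg_analyze(mat, n_draws = 500, seed = 99L)
  expect_identical(r1$per_gene, r2$per_gene)
  expect_identical(r1$combined_draws, r2$combined_draws)
  expect_true(all(r1$per_gene$p_bound >= 1 / 500))
  expect_gte(r1$combined_p_bound, 1 / 500)
  r3 <- wapdg_analyze(mat, n_draws = 500, seed = 100L)
  expect_false(identical(r1$combined_draws, r3$combined_draws))
})

test_that("per-gene WAPDG output is invariant to rescaling a single gene", {
  mat <- make_quantity_matrix(paste0("g", 1:3),
                              c(missense = 6L, control = 5L),
                              data.frame(gene_id = "g1", group = "missense", fold = 4),
                              cv = 0.25, seed = 47L)
  r1 <- wapdg_analyze(mat, n_draws = 300, seed = 7L)
  scaled <- mat$values
  scaled["g2", ] <- scaled["g2", ] * 1000   # one gene on a different raw scale
  r2 <- wapdg_analyze(expression_matrix(scaled, mat$groups), n_draws = 300, seed = 7L)
  expect_equal(r1$per_gene, r2$per_gene, tolerance = 1e-12)
  expect_equal(r1$combined_proportion, r2$combined_proportion, tolerance = 1e-12)
})

test_that("same-distribution groups keep a high combined shared proportion", {
  props <- vapply(1:50, function(i) {
    mat <- make_quantity_matrix(paste0("g", 1:5),
                                c(missense = 8L, truncating = 4L, control = 5L),
                                fold_table = NULL, cv = 0.25,
                                seed = 5000L + i)
    wapdg_analyze(mat, n_draws = 500, seed = 5000L + i)$combined_proportion
  }, numeric(1))
  expect_gt(median(props), 0.5)
})

test_that("complete separation with zero spread gives proportion 0", {
  groups <- c(p1 = "missense", p2 = "missense", c1 = "control", c2 = "control")
  x <- two_group_matrix(list(g = c(4, 4, 2, 2)), groups)
  r <- wapdg_analyze(x, n_draws = 100, seed = 3L)
  expect_equal(r$per_gene$proportion, 0)
  expect_equal(r$combined_p_bound, 1 / 100)
})

test_that("down-regulated genes enter the panel through reciprocal values", {
  spikes <- rbind(data.frame(gene_id = "up", group = "missense", fold = 5),
                  data.frame(gene_id = "dn", group = "missense", fold = 0.2))
  mat <- make_quantity_matrix(c("up", "dn"), c(missense = 8L, control = 5L),
                              spikes, cv = 0.2, seed = 53L)
  r <- wapdg_analyze(mat, direction_map = c(up = 1, dn = -1),
                     n_draws = 500, seed = 11L)
  summ <- r$group_summary
  # after inversion both genes point up in patients
  for (g in c("up", "dn")) {
    expect_gt(summ$mean[summ$gene_id == g & summ$group == "patient"],
              summ$mean[summ$gene_id == g & summ$group == "control"])
  }
  expect_lt(r$combined_proportion, 0.2)
})

test_that("blind samples classify by their combined weighted value", {
  spikes <- data.frame(gene_id = paste0("g", 1:6), group = "missense", fold = 4)
  mat <- make_quantity_matrix(paste0("g", 1:6), c(missense = 12L, control = 5L),
                              spikes, cv = 0.2, seed = 59L)
  model <- wapdg_analyze(mat, n_draws = 1000, seed = 13L)
  summ <- model$group_summary
  profile_of <- function(group) {
    m <- summ$mean[summ$group == group][match(model$gene_set,
                                              summ$gene_id[summ$group == group])]
    stats::setNames(m * model$grand_means[model$gene_set], model$gene_set)
  }
  pat <- classify_sample(profile_of("patient"), model, sample_id = "NP1")
  ctl <- classify_sample(profile_of("control"), model, sample_id = "NC1")
  mid <- classify_sample((profile_of("patient") + profile_of("control")) / 2,
                         model, sample_id = "MRX13")
  expect_identical(pat$verdict, "patient")
  expect_identical(ctl$verdict, "control")
  expect_identical(mid$verdict, "unassigned")
  expect_true(all(c("q_patient", "q_control") %in% names(pat)))
  expect_error(classify_sample(profile_of("patient")[-1], model), "missing gene")
})

test_that("a saved model classifies identically after JSON round-trip", {
  spikes <- data.frame(gene_id = paste0("g", 1:4), group = "missense", fold = 4)
  mat <- make_quantity_matrix(paste0("g", 1:4), c(missense = 8L, control = 5L),
                              spikes, cv = 0.2, seed = 61L)
  model <- wapdg_analyze(mat, n_draws = 400, seed = 17L)
  path <- withr::local_tempfile(fileext = ".json")
  write_wapdg_model(model, path)
  back <- read_wapdg_model(path)
  unknown <- stats::setNames(mat$values[, 1], rownames(mat$values))
  expect_equal(classify_sample(unknown, back, sample_id = "u")$combined_value,
               classify_sample(unknown, model, sample_id = "u")$combined_value,
               tolerance = 1e-12)
  expect_equal(back$combined_p_bound, model$combined_p_bound)
})
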