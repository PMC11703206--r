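make_scoring_model <- function(seed = 101, constrained = TRUE) {
  withr::with_seed(seed, {
    b <- energy_matrix(11, matrix(rnorm(220, 0, 0.7), 20))
    if (constrained) b <- apply_central_constraint(b)
    binding_model(b, energy_matrix(3), constrained = constrained)
  })
}

test_that("ddg matrices are negated, column-centred coefficients", {
  zero <- binding_model(energy_matrix(11))
  expect_equal(unname(ddg_matrix(zero)$values), matrix(0, 20, 11))

  m <- binding_model(energy_matrix(11))
  m$beta_s["A", 3] <- 1   # column (1, 0, ..., 0)
  dd <- ddg_matrix(m)
  expect_equal(unname(dd$values["A", 3]), -(1 - 1 / 20))
  expect_equal(unname(dd$values["C", 3]), 1 / 20)

  # a gauge shift of one column leaves the ddg matrix unchanged
  m2 <- make_scoring_model()
  dd2 <- ddg_matrix(m2)
  m3 <- m2
  m3$beta_s[, 2] <- m3$beta_s[, 2] + 0.9
  expect_equal(ddg_matrix(m3)$values, dd2$values, tolerance = 1e-12)

  # frozen column reported as-is and flagged
  expect_equal(dd2$frozen_col, 6L)
  expect_equal(unname(dd2$values["Y", 6]), 0)
  expect_equal(unname(dd2$values["A", 6]), 10)
  expect_equal(colnames(dd2$values), sprintf("%+d", -5:5))
})

test_that("log-enrichment matrices are frequency log-ratios", {
  # position 1: input A:50/C:50, bound A:90/C:10
  tab <- pepbound:::new_count_table(
    c("AG", "CG"), c(50L, 50L), c(90L, 10L))
  e <- enrichment_matrix(tab, pseudocount = 0)
  expect_equal(unname(e["A", 1]), log(0.9 / 0.5), tolerance = 1e-12)
  expect_equal(unname(e["C", 1]), log(0.1 / 0.5), tolerance = 1e-12)
  expect_equal(unname(e["G", 2]), 0)
  expect_true(is.na(e["W", 1]))   # unobserved in both libraries

  # bound identical to input: all zero
  tab2 <- pepbound:::new_count_table(c("AG", "CG"), c(3L, 7L), c(3L, 7L))
  expect_equal(unname(enrichment_matrix(tab2, pseudocount = 0.5)),
               matrix(0, 20, 2))

  # row order of the table is irrelevant
  tab3 <- tab[2:1, ]
  class(tab3) <- class(tab)
  expect_equal(enrichment_matrix(tab3, pseudocount = 0), e)

  # a residue enriched in bound but absent from input demands a pseudocount
  tabz <- pepbound:::new_count_table(c("AG", "CG", "GG"),
                                     c(5L, 5L, 0L), c(5L, 0L, 5L))
  expect_error(enrichment_matrix(tabz, pseudocount = 0), "pseudocount")
  expect_true(is.finite(enrichment_matrix(tabz, pseudocount = 0.5)["G", 1]))
})

test_that("peptide scores behave additively and dominate single offsets", {
  m <- binding_model(apply_central_constraint(energy_matrix(11)),
                     constrained = TRUE)
  expect_equal(score_peptide(m, "GGGGGYGGGGG", mode = "central"), 0)
  expect_equal(score_peptide(m, "GGGGGYGGGGG", mode = "total"),
               log(1 + 10 * exp(-10)), tolerance = 1e-12)

  # central-mode score differences reduce to coefficient differences
  m2 <- make_scoring_model(102)
  a <- "ACDEFYHIKLM"
  b <- "ACDWFYHIKLM"   # E -> W at position 4
  expect_equal(score_peptide(m2, b, "central") - score_peptide(m2, a, "central"),
               unname(m2$beta_s["W", 4] - m2$beta_s["E", 4]), tolerance = 1e-12)

  # total score dominates the best single offset (log-sum-exp dominance)
  withr::with_seed(103, peps <- random_peptides(10, fixed = c("6" = "Y")))
  for (p in peps) {
    padded <- paste0("GQSGQ", p, "GGQSG")
    best <- max(vapply(1:11, function(x)
      window_energy(m2$beta_s, substr(padded, x, x + 10)), numeric(1)))
    expect_gte(score_peptide(m2, p, "total") + 1e-12, best)
  }
})

test_that("site scans filter, sort and break ties deterministically", {
  m <- make_scoring_model(104)
  withr::with_seed(105, peps <- random_peptides(4, fixed = c("6" = "Y")))
  sites <- tibble::tibble(site_id = c("s1", "s2", "s3", "s4"),
                          peptide = c(peps[1], peps[2], peps[2], peps[3]))
  res <- scan_sites(m, sites)
  expect_equal(nrow(res), 4)
  expect_true(all(diff(res$log_affinity) <= 1e-12))
  # identical peptides score identically and order by id
  dup <- res[res$peptide == peps[2], ]
  expect_equal(dup$site_id, sort(dup$site_id))

  kept <- scan_sites(m, sites, keep_ids = c("s1"))
  expect_equal(kept$site_id, "s1")

  # the matrix argmax peptide achieves the maximum central-mode score:
  # verified exhaustively on a reduced 3-letter, 3-position model
  withr::with_seed(106, small <- matrix(rnorm(60), 20,
                                        dimnames = list(pepbound:::PB_ALPHABET, NULL)))
  sm <- binding_model(energy_matrix(3, small), energy_matrix(1),
                      flank_overlap = 0, var_len = 3)
  abc <- c("A", "C", "D")
  sub <- small[abc, ]
  combos <- expand.grid(abc, abc, abc, stringsAsFactors = FALSE)
  all_peps <- apply(combos, 1, paste, collapse = "")
  brute_best <- max(vapply(seq_len(nrow(combos)), function(i)
    sub[combos[i, 1], 1] + sub[combos[i, 2], 2] + sub[combos[i, 3], 3],
    numeric(1)))
  argmax <- paste(abc[apply(sub, 2, which.max)], collapse = "")
  expect_equal(score_peptide(sm, argmax, "central"), brute_best, tolerance = 1e-12)
  expect_equal(max(score_peptide(sm, all_peps, "central")), brute_best)
})

test_that("variant effects follow the closed form and reject central substitutions", {
  m <- make_scoring_model(107)
  wt <- "ACDEFYHIKLM"
  var <- "ACDEFYHIKAM"  # L -> A at position 10
  v <- variant_effect(m, "site", wt, var, mode = "central")
  expect_equal(v$log_ratio, unname(m$beta_s["A", 10] - m$beta_s["L", 10]),
               tolerance = 1e-12)
  vt <- variant_effect(m, "site", wt, var, mode = "total")
  expect_equal(vt$log_ratio,
               log(oracle_mode_affinity(paste0("GQSGQ", var, "GGQSG"), m$beta_s)) -
                 log(oracle_mode_affinity(paste0("GQSGQ", wt, "GGQSG"), m$beta_s)),
               tolerance = 1e-10)
  expect_equal(vt$max_log_affinity,
               max(score_peptide(m, c(wt, var))), tolerance = 1e-12)

  expect_error(variant_effect(m, "s", wt, wt), "identical")
  expect_error(variant_effect(m, "s", wt, "ACDEFFHIKLM"), "central")

  # direction calls respect the neutral band
  tiny <- binding_model(energy_matrix(11))
  tiny$beta_s["A", 2] <- 0.01
  v2 <- variant_effect(tiny, "s", "CCCCCYCCCCC", "CACCCYCCCCC", mode = "central")
  expect_equal(v2$direction, "neutral")
  tiny$beta_s["A", 2] <- 2
  v3 <- variant_effect(tiny, "s", "CCCCCYCCCCC", "CACCCYCCCCC", mode = "central")
  expect_equal(v3$direction, "gain")

  vv <- variant_effects(tiny, tibble::tibble(
    site_id = c("a", "b"), wt_peptide = c("CCCCCYCCCCC", "CACCCYCCCCC"),
    var_peptide = c("CACCCYCCCCC", "CCCCCYCCCCC")))
  expect_equal(vv$direction, c("gain", "loss"))
})

test_that("model comparison is a squared correlation over free coefficients", {
  a <- ddg_matrix(make_scoring_model(108))
  expect_equal(compare_models(a, a)$r2, 1)
  b <- a
  b$values <- -b$values
  expect_equal(compare_models(a, b)$r2, 1, tolerance = 1e-12)

  # r2 decays monotonically (on average) with added noise
  withr::with_seed(109, {
    r2s <- vapply(c(0.1, 0.5, 2), function(s) {
      mean(vapply(1:20, function(i) {
        n <- a
        n$values <- n$values + matrix(rnorm(220, 0, s), 20)
        compare_models(a, n)$r2
      }, numeric(1)))
    }, numeric(1))
  })
  expect_true(all(diff(r2s) < 0))
  expect_equal(nrow(compare_models(a, a)$data), 200)
})

test_that("K_D regression recovers exact linear relations and rejects degeneracy", {
  pred <- c(-2, -1, 0, 1.5, 3)
  kd <- exp(2 * pred + 1)
  f <- fit_kd_regression(pred, kd)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_error(fit_kd_regression(rep(1, 5), kd), "degenerate")

  # slope estimates are unbiased under noise on ln K_D
  withr::with_seed(110, {
    slopes <- vapply(1:500, function(i) {
      fit_kd_regression(pred, exp(2 * pred + 1 + rnorm(5, 0, 0.3)))$slope
    }, numeric(1))
  })
  expect_lt(abs(mean(slopes) - 2), 3 * sd(slopes) / sqrt(500))
  expect_equal(tidy(f)$r2, 1)
})

test_that("model clustering groups identical matrices first", {
  a <- ddg_matrix(make_scoring_model(111))
  b <- ddg_matrix(make_scoring_model(112))
  models <- list(m1 = a, m2 = a, m3 = b)
  hc <- cluster_models(models)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("m1", "m2"))
  expect_equal(hc$height[1], 0, tolerance = 1e-12)

  # order invariance up to labels
  hc2 <- cluster_models(list(m3 = b, m1 = a, m2 = a))
  first2 <- sort(hc2$labels[-hc2$merge[1, ]])
  expect_equal(first2, c("m1", "m2"))
})

test_that("models survive a JSON round-trip and matrices a TSV export", {
  m <- make_scoring_model(113)
  m$activities <- tibble::tibble(round = c("R1", "R2"),
                                 alpha_ns = c(0.3, 0.4), alpha_s = c(1, 2),
                                 eta_input = c(5, 6), eta_bound = c(1, 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$beta_s, m$beta_s, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$gamma, m$gamma)
  expect_equal(as.data.frame(back$activities), as.data.frame(m$activities))
  expect_equal(back$constrained, m$constrained)
  withr::with_seed(114, pep <- random_peptides(5, fixed = c("6" = "Y")))
  expect_equal(predicted_enrichment(back, pep, 2),
               predicted_enrichment(m, pep, 2), tolerance = 1e-12)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_ddg_tsv(ddg_matrix(m), tsv)
  d <- utils::read.delim(tsv, check.names = FALSE)
  expect_equal(dim(d), c(11L, 21L))
  expect_equal(names(d)[-1], pepbound:::PB_ALPHABET)
})
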