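test_that("two-way ANOVA matches a hand-worked sums-of-squares oracle", {
  mat <- matrix(c(1.2, 2.5, 0.8,
                  2.0, 3.1, 1.4), nrow = 2, byrow = TRUE)
  data <- tidyr::expand_grid(colony = c("A", "B"), zt = c(2, 6, 10)) |>
    dplyr::mutate(zscore = as.vector(t(mat)))
  got <- two_way_anova(data)
  oracle <- manual_two_way(mat)
  expect_equal(got$f_timepoint, oracle$f_timepoint)
  expect_equal(got$p_timepoint, oracle$p_timepoint)
  expect_equal(got$f_colony, oracle$f_colony)
  expect_equal(got$p_colony, oracle$p_colony)
  expect_equal(got$df_timepoint, 2)
  expect_equal(got$df_colony, 1)
  expect_equal(got$df_residual, 2)
})

test_that("equal per-timepoint means give a zero timepoint effect", {
  # every timepoint has the same mean across colonies (a latin-square
  # arrangement), so the timepoint sum of squares is exactly zero
  data <- tidyr::expand_grid(colony = c("A", "B", "C"), zt = c(2, 6, 10)) |>
    dplyr::mutate(zscore = c(1, 2, 3, 3, 1, 2, 2, 3, 1))
  got <- two_way_anova(data)
  expect_equal(got$f_timepoint, 0)
  expect_equal(got$p_timepoint, 1)
})

test_that("ANOVA is location invariant and validates its layout", {
  data <- tidyr::expand_grid(colony = c("A", "B", "C"), zt = c(2, 6, 10)) |>
    dplyr::mutate(zscore = sin(seq_len(9)))
  shifted <- dplyr::mutate(data, zscore = zscore + 100)
  expect_equal(two_way_anova(data), two_way_anova(shifted))

  expect_error(two_way_anova(data[-1, ]), "one value per")
  expect_error(two_way_anova(dplyr::filter(data, colony == "A")),
               "at least 2")
})

test_that("the compound significance rule reproduces the published calls", {
  # night-peaking strong oscillator: significant under both rules
  expect_true(classify_oscillation(0.01, 0.003, 0.79, "p_only"))
  expect_true(classify_oscillation(0.01, 0.003, 0.79, "strict"))
  # arrhythmic gene: rejected under both
  expect_false(classify_oscillation(0.13, 0.32, -0.2, "p_only"))
  expect_false(classify_oscillation(0.13, 0.32, -0.2, "strict"))
  # boundary case just below the variance-explained cutoff
  expect_true(classify_oscillation(0.01, 0.015, 0.49, "p_only"))
  expect_false(classify_oscillation(0.01, 0.015, 0.49, "strict"))
  # thresholds are inclusive
  expect_true(classify_oscillation(0.05, 0.05, 0.5, "strict"))
})

test_that("published summary rows give 4 significant genes (p_only), 3 (strict)", {
  tab <- fireant_clock_summary()
  p_only <- classify_oscillation(tab$anova_p, tab$cosine_p, tab$r2_adj,
                                 "p_only")
  expect_equal(sum(p_only), 4)
  expect_setequal(tab$gene[p_only], c("per", "cry-m", "cwo", "cyc"))
  strict <- classify_oscillation(tab$anova_p, tab$cosine_p, tab$r2_adj,
                                 "strict")
  expect_equal(sum(strict), 3)
  expect_setequal(tab$gene[strict], c("per", "cwo", "cyc"))
})

test_that("classification is monotone in its inputs", {
  set.seed(13)
  for (rule in c("p_only", "strict")) {
    ap <- runif(50); cp <- runif(50); r2a <- runif(50, -0.5, 1)
    base <- classify_oscillation(ap, cp, r2a, rule)
    better <- classify_oscillation(ap * 0.5, cp * 0.5, pmin(r2a + 0.2, 1),
                                   rule)
    expect_true(all(better >= base))
  }
})

test_that("summarize_rhythms flags phase disagreement across colonies", {
  fits <- tibble::tibble(
    gene = c("g1", "g2"), peak_zt = c(6, 2), peak_zt_grid = c(6, 2),
    amplitude_pt = c(2, 2), r2 = c(0.9, 0.9), r2_adj = c(0.85, 0.85),
    p_value = c(0.01, 0.01)
  )
  anova <- tibble::tibble(gene = c("g1", "g2"),
                          f_timepoint = c(8, 8), p_timepoint = c(0.01, 0.01))
  colony_fits <- tibble::tibble(
    gene = rep(c("g1", "g2"), each = 2),
    colony = rep(c("A", "B"), 2),
    peak_zt = c(6, 7, 2, 14) # g2 colonies disagree by 12 h
  )
  summ <- summarize_rhythms(fits, anova, colony_fits = colony_fits)
  expect_true(summ$consistent_across_colonies[summ$gene == "g1"])
  expect_false(summ$consistent_across_colonies[summ$gene == "g2"])
  expect_true(all(summ$significant))
  expect_equal(summ$rule_used, rep("p_only", 2))
})

test_that("an empty gene set yields an empty summary with full schema", {
  empty <- summarize_rhythms(
    fit_rhythms(tibble::tibble(gene = character(), zt = double(),
                               mean_z = double()), method = "ls", n_perm = 0),
    tibble::tibble(gene = character(), f_timepoint = double(),
                   p_timepoint = double())
  )
  expect_equal(nrow(empty), 0)
  expect_true(all(c("gene", "peak_zt", "anova_p", "cosine_p", "significant",
                    "consistent_across_colonies") %in% names(empty)))
})

test_that("synthetic ground truth: exactly the true oscillators are called", {
  ct <- simulate_qpcr(sim_config(seed = 99, replicate_noise_sd = 0.25))
  expr <- quantify_expression(ct, "EF1a")
  fits <- fit_rhythms(aggregate_colonies(expr), method = "ls",
                      n_perm = 499, seed = 99)
  summ <- summarize_rhythms(fits, rhythm_anova(expr), rule = "p_only")
  truth <- default_gene_panel()
  oscillators <- truth$gene[truth$amplitude_ct >= 1]
  expect_setequal(summ$gene[summ$significant], oscillators)
})
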