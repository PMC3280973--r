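test_that("chi-square 2x2 matches the closed form and the stats oracle", {
  set.seed(12)
  for (i in 1:25) {
    m <- matrix(sample(1:80, 4, replace = TRUE), 2)
    got <- chi_square_2x2(m)
    # closed form N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
    a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
    n <- sum(m)
    stat <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(got$statistic, stat)
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    # invariance under row and column swaps
    expect_equal(chi_square_2x2(m[2:1, ])$p_value, got$p_value)
    expect_equal(chi_square_2x2(m[, 2:1])$p_value, got$p_value)
  }
  ind <- chi_square_2x2(10, 10, 10, 10)
  expect_equal(ind$statistic, 0)
  expect_equal(ind$p_value, 1)
  expect_error(chi_square_2x2(0, 0, 5, 5), "fisher")
})

test_that("Fisher's exact test equals brute-force hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(1, 0, 0, 1)$p_value, 1.0)
  set.seed(14)
  for (i in 1:200) {
    n <- sample(4:200, 1)
    a <- sample(0:n, 1)
    rest <- n - a
    b <- if (rest > 0) sample(0:rest, 1) else 0
    rest <- rest - b
    c <- if (rest > 0) sample(0:rest, 1) else 0
    d <- rest - c
    if (a + b + c + d == 0) next
    got <- fisher_exact_2x2(a, b, c, d)$p_value
    expect_equal(got, oracle_fisher(a, b, c, d), tolerance = 1e-9)
    # and agrees with the standard implementation
    ref <- stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value
    expect_equal(got, ref, tolerance = 1e-7)
  }
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
})

test_that("the small-sample rule switches to Fisher for small groups only", {
  # 17-sample group: Fisher
  mll <- contingency_test(0, 17, 55, 577)
  expect_equal(mll$test_used, "fisher")
  # 23-sample group: chi-square even though one expected cell is below 5,
  # matching the reported test choice for that subgroup
  bcr <- contingency_test(6, 17, 52, 573)
  expect_equal(bcr$test_used, "chi_square")
  expect_equal(contingency_test(6, 17, 52, 573,
                                small_rule = "expected")$test_used,
               "fisher")
  big <- contingency_test(30, 70, 40, 60)
  expect_equal(big$test_used, "chi_square")
  expect_s3_class(tidy(mll), "tbl_df")
})

test_that("the published cohort counts reproduce the printed P-values", {
  counts <- cohort_counts()
  res <- counts |>
    dplyr::group_by(classification) |>
    dplyr::group_modify(~ cohort_enrichment(.x, group = in_group,
                                            deletion = deletion,
                                            weight = n)) |>
    dplyr::ungroup()
  p <- function(cl) res$p_value[res$classification == cl]
  tab <- function(cl) unlist(
    res[res$classification == cl, c("a", "b", "c", "d")])
  expect_equal(unname(tab("hyperdiploid")), c(5, 155, 55, 422))
  expect_equal(round(p("t_lineage"), 3), 0.001)
  expect_equal(round(p("hyperdiploid"), 3), 0.002)
  expect_equal(round(p("bcr_abl1"), 3), 0.003)
  expect_lt(p("etv6_runx1"), 0.001)
  expect_equal(round(p("mll"), 3), 0.385)
  expect_equal(res$test_used[res$classification == "mll"], "fisher")
  expect_equal(round(p("other"), 3), 0.155)
  expect_equal(round(p("unknown"), 3), 0.245)
})

test_that("build_tables handles level-vs-rest groups, weights and missing values", {
  cohort <- tibble::tibble(
    subgroup = c("a", "a", "b", "b", "b", NA, "a"),
    del = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, NA))
  tabs <- build_tables(cohort, subgroup, del)
  # NA group and NA deletion rows are excluded
  expect_equal(tabs$n_total, c(5, 5))
  a_row <- tabs[tabs$group_label == "a", ]
  expect_equal(unlist(a_row[c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 2, d = 1))
  # empty input gives an empty table set
  expect_equal(nrow(build_tables(cohort[0, ], subgroup, del)), 0L)
  # totals are conserved: yes+no equals the non-missing cohort size
  expect_equal(a_row$a + a_row$b + a_row$c + a_row$d, 5)
})

test_that("simulated cohorts reproduce their configured rates in the tables", {
  cfg <- simulator_config(
    seed = 31,
    n_samples = c(etv6_runx1 = 400L, hyperdiploid = 400L),
    deletion_prob = c(etv6_runx1 = 0.19, hyperdiploid = 0.031),
    subclonal_rate = 0)
  co <- simulate_cohort(cfg)
  cl <- apply_detection(co$clones)
  pos <- unique(cl$sample_id[cl$detection == "MLPA+"])
  per <- dplyr::mutate(co$samples, del = sample_id %in% pos)
  tabs <- build_tables(per, subgroup, del)
  for (g in c("etv6_runx1", "hyperdiploid")) {
    row <- tabs[tabs$group_label == g, ]
    p_hat <- row$a / (row$a + row$b)
    p_true <- cfg$deletion_prob[[g]]
    sigma <- sqrt(p_true * (1 - p_true) / 400)
    expect_lt(abs(p_hat - p_true), 3 * sigma + 1e-9)
  }
})

test_that("subclonal_summary reports PCR-only fractions per stratum", {
  # a fixture reproducing the screen structure: 89 MLPA-negative samples,
  # 16 of which carry PCR-only subclonal deletions
  samples <- tibble::tibble(
    sample_id = sprintf("m%03d", 1:89), lineage = "BCP-ALL")
  clones <- tibble::tibble(
    sample_id = sprintf("m%03d", 1:16),
    detection = "PCR-only")
  s <- subclonal_summary(clones, samples)
  expect_equal(s$n_mlpa_neg, 89L)
  expect_equal(s$n_pcr_only, 16L)
  expect_equal(s$pcr_only_fraction, 16 / 89)
  # no PCR-only clones
  s0 <- subclonal_summary(clones[0, ], samples)
  expect_equal(s0$n_pcr_only, 0L)
  expect_equal(s0$pcr_only_fraction, 0)
  # multiclonal counting: a sample with two detected clones
  clones2 <- tibble::tibble(sample_id = c("m001", "m001", "m002"),
                            detection = c("MLPA+", "PCR-only", "PCR-only"))
  s2 <- subclonal_summary(clones2, samples)
  expect_equal(s2$n_multiclonal, 1L)
})

test_that("deletion type frequencies sum to one over classified labels", {
  labels <- c(rep("III", 49), rep("V", 15), rep("VIII", 17),
              rep("I", 19), rep("novel", 3))
  freqs <- deletion_type_frequencies(labels)
  classified <- freqs[freqs$classified, ]
  expect_equal(sum(classified$proportion), 1)
  top3 <- sum(classified$proportion[classified$label %in%
                                      c("III", "V", "VIII")])
  expect_equal(top3, (49 + 15 + 17) / 100, tolerance = 1e-12)
  expect_true(is.na(freqs$proportion[freqs$label == "novel"]))

  expect_equal(deletion_type_frequencies("IV")$proportion, 1)

  # uniform simulation over 8 types: each within 3 sigma of 1/8
  set.seed(8)
  u <- sample(as.character(utils::as.roman(1:8)), 4000, replace = TRUE)
  fu <- deletion_type_frequencies(u)
  sigma <- sqrt((1 / 8) * (7 / 8) / 4000)
  expect_true(all(abs(fu$proportion - 1 / 8) <= 3 * sigma))
})
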