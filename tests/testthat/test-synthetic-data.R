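test_that("simulate_locus places distal sites at scaled distances", {
  cfg <- simulator_config(seed = 7, scale_factor = 0.01)
  locus <- simulate_locus(cfg)
  expect_s3_class(locus$distal_sites, "tbl_df")
  expect_equal(nrow(locus$distal_sites), 8L)
  # distances read back from the truth BED equal distance x scale
  expect_equal(locus$distal_sites$distance,
               round(round(seq(101000, 557000, length.out = 8)) * 0.01))
  expect_equal(locus$distal_sites$breakpoint,
               locus$hotspot$cleavage_edge + locus$distal_sites$distance)
  expect_gt(locus$locus_length, 6000)
  expect_lt(locus$locus_length, 8000)
  # geometry invariants: exon2 inside gene inside locus, hotspot in exon2
  expect_true(locus$exon2$start >= locus$gene$start &&
                locus$exon2$end <= locus$gene$end)
  expect_true(locus$gene$end <= locus$locus_length)
  expect_true(locus$hotspot$start >= locus$exon2$start &&
                locus$hotspot$end <= locus$exon2$end)
})

test_that("embedded motifs are retrievable verbatim from the sequence", {
  cfg <- simulator_config(seed = 21, scale_factor = 0.01)
  locus <- simulate_locus(cfg)
  hs <- locus$hotspot
  expect_equal(substr(locus$sequence, hs$start + 1, hs$start + 7),
               hs$heptamer)
  expect_equal(substr(locus$sequence, hs$end - 8, hs$end), hs$nonamer)
  sites <- locus$distal_sites[locus$distal_sites$has_rss, ]
  for (i in seq_len(nrow(sites))) {
    footprint <- substr(locus$sequence, sites$start[i] + 1, sites$end[i])
    # minus-strand motif: reading orientation is the reverse complement
    reading <- oracle_revcomp(footprint)
    expect_equal(substr(reading, 1, 7), sites$heptamer[i])
    expect_equal(substr(reading, nchar(reading) - 8, nchar(reading)),
                 sites$nonamer[i])
  }
})

test_that("locus simulation is deterministic and scanner recovers the truth", {
  cfg <- simulator_config(seed = 7, scale_factor = 0.01)
  a <- simulate_locus(cfg)
  b <- simulate_locus(cfg)
  expect_identical(a$sequence, b$sequence)
  expect_identical(locus_truth_bed(a), locus_truth_bed(b))

  # every embedded RSS is found with its true mismatch counts
  hits <- scan_rss(a$sequence)
  truth <- motif_truth()
  hs <- a$hotspot
  hhit <- hits[hits$start == hs$start & hits$strand == "+" &
                 hits$spacer_len == hs$spacer_len, ]
  expect_equal(nrow(hhit), 1L)
  expect_equal(hhit$heptamer_mm,
               truth$heptamer_mm[truth$label == "HOTSPOT"])
  sites <- a$distal_sites[a$distal_sites$has_rss, ]
  for (i in seq_len(nrow(sites))) {
    hit <- hits[hits$strand == "-" & hits$start == sites$start[i] &
                  hits$spacer_len == sites$spacer_len[i], ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$heptamer_mm,
                 truth$heptamer_mm[truth$label == sites$label[i]])
    expect_equal(hit$nonamer_mm,
                 truth$nonamer_mm[truth$label == sites$label[i]])
  }
  # no spurious perfect-consensus candidate in the background
  expect_equal(nrow(hits[hits$heptamer_mm == 0 & hits$nonamer_mm == 0, ]),
               0L)
})

test_that("full-scale locus spans deletions of 101 to 557 kb", {
  cfg <- simulator_config(seed = 5, scale_factor = 1)
  locus <- simulate_locus(cfg)
  expect_equal(min(locus$distal_sites$distance), 101000)
  expect_equal(max(locus$distal_sites$distance), 557000)
  expect_equal(nrow(locus$distal_sites), 8L)
})

test_that("an infeasibly small scale errors naming the minimal scale", {
  expect_error(simulate_locus(simulator_config(seed = 1,
                                               scale_factor = 1e-4)),
               "minimal feasible scale")
})

test_that("simulated deletions honor the 12/23 rule and the TdT model", {
  cfg <- simulator_config(seed = 13, scale_factor = 0.01)
  locus <- simulate_locus(cfg)
  set.seed(131)
  ev <- simulate_deletion(locus, n = 50, config = cfg)
  expect_true(all(ev$proximal_spacer_class == 23))
  expect_true(all(ev$distal_spacer_class == 12 | !ev$has_rss))
  expect_true(all(ev$ins_len >= 1 & ev$ins_len <= 10))
  expect_equal(ev$del_length, ev$distal_break - ev$proximal_break)

  # zero-length TdT distribution: junction is the exact flank concatenation
  cfg0 <- simulator_config(seed = 13, scale_factor = 0.01,
                           tdt_len = c(min = 0L, max = 0L), jitter = FALSE)
  set.seed(132)
  ev0 <- simulate_deletion(locus, n = 5, config = cfg0)
  expect_true(all(ev0$inserted_nt == ""))
  flank <- cfg0$flank
  for (i in 1:5) {
    expect_equal(ev0$junction[i],
                 paste0(substr(locus$sequence,
                               ev0$proximal_break[i] - flank + 1,
                               ev0$proximal_break[i]),
                        substr(locus$sequence, ev0$distal_break[i] + 1,
                               ev0$distal_break[i] + flank)))
  }
})

test_that("distal sites are drawn uniformly across deletion events", {
  cfg <- simulator_config(seed = 17, scale_factor = 0.01)
  locus <- simulate_locus(cfg)
  set.seed(171)
  ev <- simulate_deletion(locus, n = 10000, config = cfg)
  counts <- table(ev$site_label)
  expect_equal(length(counts), 8L)
  # each site frequency within 3 sigma of binomial(n, 1/8)
  expected <- 10000 / 8
  sigma <- sqrt(10000 * (1 / 8) * (7 / 8))
  expect_true(all(abs(counts - expected) <= 3 * sigma))
})

test_that("detection labels follow the threshold rules monotonically", {
  labels <- apply_detection(
    tibble::tibble(clonal_fraction = c(0.5, 0.30, 0.05, 0.01, 0.001)))
  expect_equal(labels$detection,
               c("MLPA+", "MLPA+", "PCR-only", "PCR-only", "undetected"))
  # monotone: sorted fractions give non-increasing detectability
  set.seed(4)
  f <- sort(runif(100), decreasing = TRUE)
  lv <- apply_detection(tibble::tibble(clonal_fraction = f))$detection
  rank <- c("MLPA+" = 3, "PCR-only" = 2, "undetected" = 1)[lv]
  expect_true(all(diff(rank) <= 0))
})

test_that("simulated cohorts honor lineage restrictions and determinism", {
  cfg <- simulator_config(
    seed = 23,
    n_samples = c(etv6_runx1 = 40L, t_all = 30L, normal = 10L),
    deletion_prob = c(etv6_runx1 = 0.19, t_all = 0, normal = 0))
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$samples), 80L)
  # T-ALL and normal samples never carry deletions
  tn <- co$clones$lineage %in% c("T-ALL", "normal")
  expect_equal(sum(tn), 0L)
  # clonal fractions per sample sum to at most 1
  sums <- tapply(co$clones$clonal_fraction, co$clones$sample_id, sum)
  expect_true(all(sums <= 1))
  # determinism: identical config gives identical clone table
  co2 <- simulate_cohort(cfg)
  expect_identical(co$clones, co2$clones)
  expect_identical(cohort_table(co), cohort_table(co2))
})

test_that("an all-zero-probability cohort is valid and deletion-free", {
  cfg <- simulator_config(
    seed = 2, n_samples = c(other = 20L, t_all = 5L),
    deletion_prob = c(other = 0, t_all = 0), subclonal_rate = 0)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$clones), 0L)
  tab <- cohort_table(co)
  expect_equal(nrow(tab), 25L)
  expect_true(all(is.na(tab$clone_id)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_tsv(co, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(back),
               c("sample_id", "lineage", "subgroup", "timepoint",
                 "clone_id", "deletion_type", "clonal_fraction"))
})

test_that("zero group sizes error", {
  expect_error(
    simulator_config(seed = 1, n_samples = c(other = 0L),
                     deletion_prob = c(other = 0.1)),
    "at least one group")
})

test_that("simulated Ct tables invert exactly at zero noise", {
  chip <- simulate_chip_ct(sigma = 0, seed = 5)
  rec <- pct_recovery(chip)
  expect_equal(rec$pct_recovery, rec$true_recovery, tolerance = 1e-12)

  truth <- tibble::tibble(sample_id = c("Nalm6", "REH", "SUP-B15"),
                          true_fold = c(1, 2, 0.25))
  qp <- simulate_qpcr_ct(truth, sigma = 0, seed = 5)
  folds <- delta_delta_ct(qp, calibrator = "Nalm6")
  expect_equal(folds$fold_change[match(truth$sample_id, folds$sample_id)],
               truth$true_fold, tolerance = 1e-12)
  expect_error(simulate_chip_ct(sigma = -1), "sigma")
  expect_error(simulate_qpcr_ct(truth, sigma = -0.1), "sigma")
})

test_that("noisy Ct tables recover fold changes within a few percent", {
  truth <- tibble::tibble(sample_id = c("cal", "s"), true_fold = c(1, 2))
  set.seed(55)
  folds <- replicate(100, {
    qp <- simulate_qpcr_ct(truth, calibrator = "cal", sigma = 0.1)
    res <- delta_delta_ct(qp, calibrator = "cal")
    res$fold_change[res$sample_id == "s"]
  })
  expect_lt(abs(mean(folds) - 2) / 2, 0.05)
})
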