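test_that("decompose_junction separates flanks and a non-templated insertion", {
  # unambiguous case: the insertion "GA" extends into neither flank
  call <- decompose_junction("AAAACCGATTGGCC", "AAAACCTT", "GGTTGGCC",
                             min_anchor = 4)
  expect_equal(call$status, "ok")
  expect_equal(call$proximal_break, 6L)
  expect_equal(call$distal_break, 2L)
  expect_equal(call$inserted_nt, "GA")
  expect_equal(call$microhomology_len, 0L)
  # brute force over all consistent decompositions: among those anchored on
  # both sides, the minimal-insertion decomposition is unique and agrees
  all_dec <- oracle_decompositions("AAAACCGATTGGCC", "AAAACCTT", "GGTTGGCC")
  s_len <- nchar("AAAACCGATTGGCC") - all_dec$proximal_break -
    nchar(all_dec$inserted_nt)
  anchored <- all_dec[all_dec$proximal_break >= 4 & s_len >= 4, ]
  minimal <- anchored[nchar(anchored$inserted_nt) ==
                        min(nchar(anchored$inserted_nt)), ]
  expect_equal(nrow(minimal), 1L)
  expect_equal(minimal$inserted_nt, "GA")
  expect_equal(minimal$proximal_break, 6L)
})

test_that("decompose_junction follows the maximal-prefix convention when ambiguous", {
  # here the insertion's first base G matches the proximal reference's next
  # base, so (6, "GA") and (7, "A") both reconstruct the junction; the
  # documented greedy rule takes the longest proximal match
  call <- decompose_junction("AAAACCGATTGGCC", "AAAACCGG", "CCTTGGCC",
                             min_anchor = 4)
  expect_equal(call$proximal_break, 7L)
  expect_equal(call$inserted_nt, "A")
  expect_equal(call$distal_break, 2L)
  # both decompositions are present in the brute-force enumeration
  all_dec <- oracle_decompositions("AAAACCGATTGGCC", "AAAACCGG", "CCTTGGCC")
  keys <- paste(all_dec$proximal_break, all_dec$inserted_nt)
  expect_true(all(c("6 GA", "7 A") %in% keys))
})

test_that("an exact concatenation decomposes with empty insertion", {
  set.seed(9)
  prox <- random_dna(40)
  dist <- random_dna(40)
  junction <- paste0(substr(prox, 1, 25), substr(dist, 11, 40))
  call <- decompose_junction(junction, prox, dist)
  expect_equal(call$status, "ok")
  expect_equal(call$inserted_nt, "")
  # reconstruction identity holds byte-for-byte
  expect_equal(reassemble_junction(call, prox, dist, nchar(junction)),
               junction)
})

test_that("overlapping flank matches are reported as microhomology", {
  # construct references sharing the 3-mer "TGC" at the junction point
  prox <- paste0("AAACCCGGGTTTACG", "TGC", "AAAA")
  dist <- paste0("CCCC", "TGC", "GATCGATCGATTTT")
  junction <- paste0("AAACCCGGGTTTACG", "TGC", "GATCGATCGATTTT")
  call <- decompose_junction(junction, prox, dist, min_anchor = 5)
  expect_equal(call$status, "ok")
  expect_equal(call$microhomology_len, 3L)
  expect_equal(call$microhomology_seq, "TGC")
  expect_equal(call$inserted_nt, "")
  # canonical proximal-most split: retained proximal stops before the overlap
  expect_equal(call$proximal_break, 15L)
  expect_equal(call$distal_break, 4L)
  expect_equal(reassemble_junction(call, prox, dist, nchar(junction)),
               junction)
})

test_that("junctions that do not anchor are flagged, not errored", {
  set.seed(10)
  unrelated <- random_dna(80)
  prox <- random_dna(60)
  dist <- random_dna(60)
  call <- decompose_junction(unrelated, prox, dist)
  expect_equal(call$status, "unrelated")
  expect_true(is.na(call$proximal_break))
  # one-sided anchor
  half <- paste0(substr(prox, 1, 30), random_dna(40))
  expect_equal(decompose_junction(half, prox, dist)$status,
               "partial_anchor")
})

test_that("round trip: simulated deletion events decompose to their truth", {
  cfg <- simulator_config(seed = 19, scale_factor = 0.01,
                          tdt_len = c(min = 1L, max = 10L))
  locus <- simulate_locus(cfg)
  set.seed(1902)
  ev <- simulate_deletion(locus, n = 300, config = cfg)
  calls <- decompose_junctions(ev)
  expect_true(all(calls$status == "ok"))
  expect_equal(calls$proximal_break, ev$proximal_break_ref)
  expect_equal(calls$distal_break, ev$distal_break_ref)
  expect_equal(calls$inserted_nt, ev$inserted_nt)
  # reconstruction identity on every call
  rebuilt <- vapply(seq_len(nrow(ev)), function(i) {
    reassemble_junction(calls[i, ], ev$proximal_ref[i], ev$distal_ref[i],
                        nchar(ev$junction[i]))
  }, character(1))
  expect_equal(rebuilt, ev$junction)
})

test_that("cluster_breakpoints performs single-linkage grouping", {
  # chain rule: {0,10} link at tolerance 10, 21 starts a new cluster
  cl <- cluster_breakpoints(c(0, 10, 21), tolerance = 10)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$members[[1]], c(0, 10))
  expect_equal(cl$members[[2]], 21)
  expect_equal(cl$cluster_id, c("I", "II"))

  expect_equal(nrow(cluster_breakpoints(rep(500, 7))), 1L)

  # eight well-separated groups give eight clusters labelled I..VIII
  set.seed(3)
  centers <- seq(1000, 8000, by = 1000)
  pos <- unlist(lapply(centers, function(c) c + sample(-3:3, 5, TRUE)))
  cl8 <- cluster_breakpoints(pos, tolerance = 10)
  expect_equal(nrow(cl8), 8L)
  expect_equal(cl8$cluster_id, as.character(utils::as.roman(1:8)))
  expect_error(cluster_breakpoints(integer()), "non-empty")
})

test_that("hotspot_window finds the minimal interval for a fraction", {
  w <- hotspot_window(c(5, 6, 7, 8, 100), fraction = 0.8)
  expect_equal(w$window_length, 4L)
  expect_equal(c(w$start, w$end), c(5L, 8L))

  expect_equal(hotspot_window(42, fraction = 1)$window_length, 1L)

  # matches the exhaustive minimal-interval search on random inputs
  set.seed(77)
  for (i in 1:20) {
    pos <- sample.int(200, sample(3:40, 1), replace = TRUE)
    f <- runif(1, 0.3, 1)
    got <- hotspot_window(pos, f)
    want <- oracle_hotspot(pos, f)
    expect_equal(got$window_length, want$len)
    expect_equal(got$start, want$start)
  }
  expect_error(hotspot_window(integer(), 0.5), "non-empty")
})

test_that("a cohort with 75% of breakpoints in a 10 bp core yields a <=10 bp window", {
  # deterministic construction of the stated proportions: 75 breakpoints
  # inside a 10 bp stretch, 25 spread over the surrounding region
  set.seed(123)
  core <- 650 + sample(0:9, 75, replace = TRUE)
  flank <- 650 + sample(c(-12:-1, 10:20), 25, replace = TRUE)
  w <- hotspot_window(c(core, flank), fraction = 0.75)
  expect_lte(w$window_length, 10L)
  # and the full spread stays within the 33 bp region
  w_all <- hotspot_window(c(core, flank), fraction = 1)
  expect_lte(w_all$window_length, 33L)
})

test_that("classify_deletion maps breakpoints to catalog labels or novel", {
  catalog <- cluster_breakpoints(c(1000, 2000, 3000), tolerance = 10)
  expect_equal(classify_deletion(2000, catalog)$label, "II")
  # a breakpoint 2 kb away from the catalog is novel at tolerance 50
  expect_equal(classify_deletion(5000, catalog, tolerance = 50)$label,
               "novel")
  # equidistant between clusters I and II: lower-position label wins
  expect_equal(classify_deletion(1500, catalog, tolerance = 600)$label, "I")
  expect_error(classify_deletion(1, catalog[0, ]), "non-empty")
})

test_that("count_unique_junctions keys on breakpoints plus insertion", {
  calls <- tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s2", "s2", "s2", "s2", "s2"),
    status = "ok",
    proximal_break = c(60L, 60L, 60L, 60L, 61L, 62L, 63L, 63L),
    distal_break = c(30L, 30L, 30L, 30L, 30L, 30L, 30L, 30L),
    inserted_nt = c("AA", "AA", "CC", "G", "G", "G", "T", "T")
  )
  counts <- count_unique_junctions(calls)
  # s1: duplicate AA collapses, CC differs -> 2 unique
  expect_equal(counts$n_unique_junctions[counts$sample_id == "s1"], 2L)
  # s2: four distinct breakpoints/insertions -> 4 independent subclones
  expect_equal(counts$n_unique_junctions[counts$sample_id == "s2"], 4L)
})
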