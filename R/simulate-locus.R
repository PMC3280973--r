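#' Cryptic RSS motifs at the recurrent deletion breakpoints
#'
#' The validated heptamer/spacer/nonamer triples flanking the breakpoint
#' hotspot (a 23-RSS in the gene's second exon) and the recurrent
#' centromeric breakpoints of deletion types I-VIII. All but one of the
#' centromeric breakpoints harbor a 12-class RSS; type II has none, and its
#' motif fields are NA.
#'
#' @return A tibble: `label`, `spacer_class`, `heptamer`, `spacer_len`,
#'   `nonamer`, `has_rss`.
#' @export
#' @examples
#' breakpoint_rss_motifs()
breakpoint_rss_motifs <- function() {
  tibble::tribble(
    ~label,    ~spacer_class, ~heptamer, ~spacer_len, ~nonamer,
    "HOTSPOT", 23L,           "CACTCTG", 23L,         "ACAGAATTG",
    "I",       12L,           "CACAGTA", 12L,         "CCAGGACAT",
    "II",      NA_integer_,   NA,        NA_integer_, NA,
    "III",     12L,           "CACAATG", 13L,         "ACTGAAATG",
    "IV",      12L,           "CACAGCT", 12L,         "ACATTTTCA",
    "V",       12L,           "CACTGCA", 12L,         "GCAATAACC",
    "VI",      12L,           "CACAGAG", 13L,         "ACAATATAG",
    "VII",     12L,           "CACTGTG", 12L,         "ATATATTCT",
    "VIII",    12L,           "CACAGTG", 12L,         "ACAATTAAT"
  ) |>
    dplyr::mutate(has_rss = !is.na(.data$heptamer))
}

# centromeric breakpoint distances from the hotspot at full scale:
# eight positions spanning 101-557 kb, endpoints fixed, interior spacing even
.base_distances <- function() {
  round(seq(101000, 557000, length.out = 8))
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# overwrite locus[start0, start0 + nchar(insert)) (0-based) with `insert`
.splice <- function(sequence, start0, insert) {
  paste0(substr(sequence, 1L, start0),
         insert,
         substr(sequence, start0 + nchar(insert) + 1L, nchar(sequence)))
}

#' Simulate a two-exon locus carrying a breakpoint hotspot and cryptic RSSs
#'
#' Generates a synthetic locus emulating the architecture behind recurrent
#' RAG-mediated microdeletions: a two-exon gene annotated on the minus
#' strand, a 23-class RSS at the recombination hotspot in exon 2 (plus
#' strand of the stored sequence, heptamer facing the deleted DNA) and
#' eight centromeric deletion target sites downstream at distances spanning
#' 101-557 kb at full scale (`scale_factor = 1`), seven of which carry a
#' minus-strand 12-class RSS whose heptamer faces back toward the hotspot.
#' Deletion of the DNA between the hotspot RSS and a distal site removes
#' both RSS footprints, so the site's recorded `breakpoint` equals the
#' hotspot cleavage edge plus the site's distance.
#'
#' The background is i.i.d. uniform ACGT, rejection-sampled until it
#' contains no spurious zero-mismatch RSS candidate, so truth is unambiguous
#' at mismatch 0 while near-consensus background noise remains.
#'
#' @param config A [simulator_config()]; `scale_factor` and `seed` are used.
#' @return An object of class `ragdel_locus`: a list with `sequence`,
#'   `locus_length`, `scale_factor`, `gene`, `exon1`, `exon2` (0-based
#'   half-open interval tibbles), `hotspot` (one-row embedded-RSS tibble
#'   with footprint coordinates and `cleavage_edge`), and `distal_sites`
#'   (tibble of the eight target sites with `distance`, `breakpoint`,
#'   footprint coordinates and motif fields).
#' @export
#' @examples
#' locus <- simulate_locus(simulator_config(seed = 7, scale_factor = 0.01))
#' locus$distal_sites[, c("label", "distance", "breakpoint")]
simulate_locus <- function(config = simulator_config()) {
  stopifnot(config$scale_factor > 0)
  set.seed(.child_seed(config$seed, "locus"))
  f <- config$scale_factor
  dists <- round(.base_distances() * f)

  motifs <- breakpoint_rss_motifs()
  hot <- motifs[motifs$label == "HOTSPOT", ]
  distal <- motifs[motifs$label != "HOTSPOT", ]
  foot_len <- function(spacer) 16L + spacer  # heptamer + spacer + nonamer

  # feasibility: distal footprints (up to 29 bp for 12-class) and the
  # hotspot footprint (39 bp) must not overlap across sites
  max_foot <- max(foot_len(distal$spacer_len), na.rm = TRUE)
  gaps <- diff(c(0, dists))
  if (any(gaps < max(max_foot, foot_len(hot$spacer_len)) + 1L)) {
    f_min <- (max_foot + foot_len(hot$spacer_len) + 2) /
      min(diff(c(0, .base_distances())))
    stop(sprintf(
      "scale_factor %.2g places distal sites closer than an RSS footprint; minimal feasible scale is about %.2g",
      f, f_min), call. = FALSE)
  }

  # fixed-size gene scaffold; intron scales, margins stay sequence-safe
  exon1_start <- 200L
  exon1_len <- 200L
  intron_len <- max(100L, round(10000 * f))
  exon2_start <- exon1_start + exon1_len + intron_len
  exon2_len <- 400L
  hot_h_start <- exon2_start + 150L  # heptamer (= footprint) start, 0-based
  hot_span <- foot_len(hot$spacer_len)
  locus_length <- hot_h_start + max(dists) + 400L

  embed_one <- function(sequence, site) {
    # returns list(sequence, start, end, spacer_seq)
    if (site$strand == "+") {
      motif <- paste0(site$heptamer, .rand_dna(site$spacer_len), site$nonamer)
      start <- site$anchor
    } else {
      motif <- .revcomp(paste0(site$heptamer, .rand_dna(site$spacer_len),
                               site$nonamer))
      start <- site$anchor - nchar(motif)
    }
    list(sequence = .splice(sequence, start, motif),
         start = start, end = start + nchar(motif))
  }

  for (attempt in seq_len(25L)) {
    sequence <- .rand_dna(locus_length)

    hotspot <- tibble::tibble(
      label = "HOTSPOT", strand = "+", spacer_class = hot$spacer_class,
      spacer_len = hot$spacer_len, heptamer = hot$heptamer,
      nonamer = hot$nonamer, anchor = hot_h_start
    )
    emb <- embed_one(sequence, hotspot)
    sequence <- emb$sequence
    hotspot$start <- emb$start
    hotspot$end <- emb$end
    hotspot$heptamer_start <- emb$start
    hotspot$cleavage_edge <- emb$start  # deleted DNA begins at the footprint

    sites <- distal |>
      dplyr::mutate(
        strand = "-",
        distance = dists,
        breakpoint = hot_h_start + dists,  # cleavage edge = footprint end
        anchor = .data$breakpoint
      )
    starts <- ends <- rep(NA_integer_, nrow(sites))
    for (i in seq_len(nrow(sites))) {
      if (!sites$has_rss[i]) next
      emb <- embed_one(sequence, sites[i, ])
      sequence <- emb$sequence
      starts[i] <- emb$start
      ends[i] <- emb$end
    }
    sites$start <- starts
    sites$end <- ends
    sites$heptamer_start <- ifelse(is.na(ends), NA_integer_, ends - 7L)

    # reject backgrounds with any spurious perfect-consensus RSS; embedded
    # motifs all deviate from consensus, so any 0/0 hit is background noise
    perfect <- scan_rss(sequence, max_heptamer_mm = 0, max_nonamer_mm = 0)
    if (nrow(perfect) == 0L) {
      locus <- structure(list(
        sequence = sequence,
        locus_length = locus_length,
        scale_factor = f,
        seed = config$seed,
        gene = tibble::tibble(start = exon1_start,
                              end = exon2_start + exon2_len, strand = "-"),
        exon1 = tibble::tibble(start = exon1_start,
                               end = exon1_start + exon1_len),
        exon2 = tibble::tibble(start = exon2_start,
                               end = exon2_start + exon2_len),
        hotspot = hotspot,
        distal_sites = dplyr::select(sites, "label", "has_rss", "strand",
                                     "spacer_class", "spacer_len",
                                     "heptamer", "nonamer", "distance",
                                     "breakpoint", "start", "end",
                                     "heptamer_start")
      ), class = "ragdel_locus")
      return(locus)
    }
  }
  stop("failed to sample a background free of spurious consensus RSSs",
       call. = FALSE)
}

#' @export
print.ragdel_locus <- function(x, ...) {
  cat(sprintf(
    "<ragdel_locus> %s bp (scale %.3g), hotspot 23-RSS at %d, %d distal sites (%d with 12-RSS)\n",
    format(x$locus_length, big.mark = ","), x$scale_factor,
    x$hotspot$heptamer_start, nrow(x$distal_sites),
    sum(x$distal_sites$has_rss)))
  invisible(x)
}

#' Truth intervals of a simulated locus as a BED-style tibble
#'
#' @param locus A `ragdel_locus`.
#' @return A tibble in BED6 layout (`chrom`, `start`, `end`, `name`,
#'   `score`, `strand`; 0-based half-open) covering the gene, exons,
#'   hotspot RSS and distal sites (RSS footprint where present, otherwise
#'   the 1-bp breakpoint).
#' @export
locus_truth_bed <- function(locus) {
  stopifnot(inherits(locus, "ragdel_locus"))
  sites <- locus$distal_sites
  dplyr::bind_rows(
    tibble::tibble(chrom = "locus", start = locus$gene$start,
                   end = locus$gene$end, name = "gene", score = 0L,
                   strand = locus$gene$strand),
    tibble::tibble(chrom = "locus", start = locus$exon1$start,
                   end = locus$exon1$end, name = "exon1", score = 0L,
                   strand = "-"),
    tibble::tibble(chrom = "locus", start = locus$exon2$start,
                   end = locus$exon2$end, name = "exon2", score = 0L,
                   strand = "-"),
    tibble::tibble(chrom = "locus", start = locus$hotspot$start,
                   end = locus$hotspot$end, name = "RSS23_HOTSPOT",
                   score = 0L, strand = locus$hotspot$strand),
    tibble::tibble(
      chrom = "locus",
      start = ifelse(sites$has_rss, sites$start, sites$breakpoint),
      end = ifelse(sites$has_rss, sites$end, sites$breakpoint + 1L),
      name = ifelse(sites$has_rss, paste0("RSS12_", sites$label),
                    paste0("BREAKPOINT_", sites$label)),
      score = 0L,
      strand = ifelse(sites$has_rss, sites$strand, ".")
    )
  )
}

#' Simulate RAG-type deletion events on a simulated locus
#'
#' Each event joins the hotspot 23-RSS to one of the distal target sites
#' (uniformly chosen), honoring the 12/23 rule where the site carries an
#' RSS. The junction is built as proximal flank + non-templated insertion +
#' distal flank. Breakpoints are placed at the RSS cleavage edges and, when
#' `jitter` is enabled (the default), perturbed to emulate end processing:
#' the telomeric (proximal) breakpoint falls inside a 10-bp core with
#' probability `hotspot_core_prob` and otherwise inside the surrounding
#' 33-bp region; the centromeric breakpoint receives +/- 5 bp of jitter.
#' Insertion lengths are drawn uniformly on `tdt_len` and, by default,
#' resampled so the insertion cannot be extended into either flank, which
#' keeps the generating decomposition unique.
#'
#' @param locus A `ragdel_locus`.
#' @param n Number of events.
#' @param config A [simulator_config()] supplying `tdt_len`, `flank`, `ext`,
#'   `jitter`, `hotspot_core_prob` and `non_extendable`.
#' @param site_labels Optional vector of site labels to draw from (default:
#'   all sites).
#' @return A tibble with one event per row: `event_id`, `site_label`,
#'   `has_rss`, `proximal_spacer_class`, `distal_spacer_class`,
#'   `proximal_break`, `distal_break` (0-based locus coordinates),
#'   `del_length`, `inserted_nt`, `ins_len`, `junction`, `proximal_ref`,
#'   `distal_ref`, `prox_ref_start`, `dist_ref_start`,
#'   `proximal_break_ref`, `distal_break_ref`.
#' @details Uses the current RNG state; seed it (or go through
#'   [simulate_cohort()]) for reproducibility.
#' @export
simulate_deletion <- function(locus, n = 1, config = simulator_config(),
                              site_labels = NULL) {
  stopifnot(inherits(locus, "ragdel_locus"), n >= 1)
  sites <- locus$distal_sites
  if (!is.null(site_labels)) sites <- sites[sites$label %in% site_labels, ]
  if (!nrow(sites)) stop("no distal target sites to draw from", call. = FALSE)
  if (!nrow(locus$hotspot) || !any(locus$distal_sites$has_rss)) {
    stop("locus must carry a hotspot 23-RSS and at least one distal 12-RSS",
         call. = FALSE)
  }
  flank <- config$flank
  ext <- config$ext
  tdt <- config$tdt_len
  chars <- strsplit(locus$sequence, "", fixed = TRUE)[[1]]

  draw_insert <- function(len, prox_next, dist_prev) {
    if (len == 0L) return("")
    for (i in seq_len(200L)) {
      ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      if (!config$non_extendable ||
          (ins[1] != prox_next && ins[len] != dist_prev)) {
        return(paste(ins, collapse = ""))
      }
    }
    paste(ins, collapse = "")
  }

  idx <- sample.int(nrow(sites), n, replace = TRUE)
  h0 <- locus$hotspot$cleavage_edge
  out <- vector("list", n)
  for (e in seq_len(n)) {
    s <- sites[idx[e], ]
    if (config$jitter) {
      core <- 0:9
      outer <- c(-12:-1, 10:20)  # 33-bp region around the core
      off_p <- if (stats::runif(1) < config$hotspot_core_prob) {
        sample(core, 1)
      } else {
        sample(outer, 1)
      }
      off_d <- sample(-5:5, 1)
    } else {
      off_p <- 0L
      off_d <- 0L
    }
    pb <- h0 + off_p
    db <- s$breakpoint + off_d
    len <- tdt[["min"]] + sample.int(tdt[["max"]] - tdt[["min"]] + 1L, 1) - 1L
    ins <- draw_insert(len, chars[pb + 1L], chars[db])
    prox_flank <- substr(locus$sequence, pb - flank + 1L, pb)
    dist_flank <- substr(locus$sequence, db + 1L, db + flank)
    out[[e]] <- tibble::tibble(
      event_id = e,
      site_label = s$label,
      has_rss = s$has_rss,
      proximal_spacer_class = locus$hotspot$spacer_class,
      distal_spacer_class = s$spacer_class,
      proximal_break = pb,
      distal_break = db,
      del_length = db - pb,
      inserted_nt = ins,
      ins_len = nchar(ins),
      junction = paste0(prox_flank, ins, dist_flank),
      proximal_ref = substr(locus$sequence, pb - flank + 1L, pb + ext),
      distal_ref = substr(locus$sequence, db - ext + 1L, db + flank),
      prox_ref_start = pb - flank,
      dist_ref_start = db - ext,
      proximal_break_ref = flank,
      distal_break_ref = ext
    )
  }
  dplyr::bind_rows(out)
}
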