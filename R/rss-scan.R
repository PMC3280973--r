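#' Recombination signal sequence (RSS) consensus
#'
#' The canonical RSS recognized by the RAG recombinase consists of a conserved
#' heptamer (consensus `CACAGTG`) and nonamer (consensus `ACAAAAACC`)
#' separated by a non-conserved spacer of 12 +/- 1 bp (a "12-RSS") or
#' 23 +/- 1 bp (a "23-RSS").
#'
#' @return A list with elements `heptamer`, `nonamer`, and `spacer_classes`
#'   (a named list mapping class `"12"` to spacer lengths 11:13 and `"23"`
#'   to 22:24).
#' @export
#' @examples
#' rss_consensus()
rss_consensus <- function() {
  list(
    heptamer = "CACAGTG",
    nonamer = "ACAAAAACC",
    spacer_classes = list(`12` = 11:13, `23` = 22:24)
  )
}

#' Position-wise mismatch count between two equal-length k-mers
#'
#' Hamming distance over the DNA alphabet. Used to score candidate heptamers
#' and nonamers against the RSS consensus.
#'
#' @param observed Character vector of k-mers.
#' @param consensus A single k-mer of the same length.
#' @return Integer vector of mismatch counts.
#' @export
#' @examples
#' mismatch_count("CACTCTG", "CACAGTG")  # 2
mismatch_count <- function(observed, consensus) {
  if (length(consensus) != 1L) {
    stop("`consensus` must be a single k-mer", call. = FALSE)
  }
  k <- nchar(consensus)
  if (any(nchar(observed) != k)) {
    stop("`observed` and `consensus` must have equal lengths", call. = FALSE)
  }
  cons <- strsplit(consensus, "", fixed = TRUE)[[1]]
  vapply(strsplit(observed, "", fixed = TRUE), function(ch) {
    sum(ch != cons)
  }, integer(1))
}

# Mismatch profile of every k-window of `chars` against `cons` (split k-mer).
# Returns a vector m where m[i] is the Hamming distance of chars[i .. i+k-1];
# windows touching an N (or running off the end) are NA.
.window_mismatches <- function(chars, cons) {
  n <- length(chars)
  k <- length(cons)
  if (n < k) return(integer(0))
  m <- integer(n - k + 1L)
  bad <- logical(n - k + 1L)
  for (j in seq_len(k)) {
    window <- chars[j:(n - k + j)]
    m <- m + (window != cons[j])
    bad <- bad | window == "N"
  }
  m[bad] <- NA_integer_
  m
}

.check_dna <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop("`sequence` must be a single character string", call. = FALSE)
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters other than A, C, G, T, N", call. = FALSE)
  }
  invisible(sequence)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Scan one strand (sequence given in reading orientation). Coordinates are
# 0-based offsets of the heptamer start within the *given* sequence.
.scan_one_strand <- function(chars, spacer_lens, max_h, max_n, require_cac,
                             weights) {
  cons <- rss_consensus()
  hep <- strsplit(cons$heptamer, "")[[1]]
  non <- strsplit(cons$nonamer, "")[[1]]
  n <- length(chars)
  hmm <- .window_mismatches(chars, hep)
  nmm <- .window_mismatches(chars, non)
  cac_ok <- if (require_cac && n >= 3) {
    ok <- chars[seq_len(n - 2L)] == "C" &
      chars[seq_len(n - 2L) + 1L] == "A" &
      chars[seq_len(n - 2L) + 2L] == "C"
    ok
  } else NULL

  out <- vector("list", length(spacer_lens))
  for (i in seq_along(spacer_lens)) {
    s <- spacer_lens[i]
    span <- 16L + s  # heptamer + spacer + nonamer
    if (n < span) next
    idx <- seq_len(n - span + 1L)           # 1-based heptamer starts
    nidx <- idx + 7L + s                    # 1-based nonamer starts
    keep <- !is.na(hmm[idx]) & !is.na(nmm[nidx]) &
      hmm[idx] <= max_h & nmm[nidx] <= max_n
    if (!is.null(cac_ok)) keep <- keep & cac_ok[idx]
    if (!any(keep)) next
    idx <- idx[keep]
    out[[i]] <- tibble::tibble(
      pos0 = idx - 1L,
      spacer_len = s,
      heptamer_mm = hmm[idx],
      nonamer_mm = nmm[idx + 7L + s]
    )
  }
  dplyr::bind_rows(out)
}

#' Scan DNA for candidate (cryptic) recombination signal sequences
#'
#' Exhaustively enumerates every heptamer/spacer/nonamer window on both
#' strands, scores heptamer and nonamer against the RSS consensus by
#' position-wise mismatches, and keeps candidates within the mismatch
#' thresholds. The default thresholds admit every validated cryptic RSS
#' reported at breakpoints of this deletion class (heptamer up to 3
#' mismatches with the invariant `CAC` anchor, nonamer up to 6 mismatches).
#'
#' Coordinates are 0-based, half-open, on the plus strand: `start`/`end`
#' delimit the full RSS footprint (heptamer + spacer + nonamer) and
#' `heptamer_start` is the plus-strand offset of the heptamer's leftmost
#' base. For minus-strand candidates `heptamer_seq` and `nonamer_seq` are
#' reported in reading (minus-strand) orientation.
#'
#' @param sequence A DNA string over `A,C,G,T,N` (windows containing `N` are
#'   skipped) or a length-1 [Biostrings::DNAStringSet].
#' @param spacer_class `"both"` (default), `"12"` or `"23"`.
#' @param max_heptamer_mm Maximum heptamer mismatches (default 3).
#' @param max_nonamer_mm Maximum nonamer mismatches (default 6).
#' @param require_cac Require the functionally invariant `CAC` at heptamer
#'   positions 1-3 (default `TRUE`); when `TRUE`, mismatches can only occur
#'   in heptamer positions 4-7.
#' @param weights Integer weights `c(heptamer=, nonamer=)` for the combined
#'   score `total_score` (default 2 and 1: cleavage occurs at the heptamer).
#' @param contig Contig name recorded in the output (default `"seq"`).
#' @return A tibble of candidates sorted by ascending `total_score` then
#'   position, with columns `contig`, `start`, `end`, `heptamer_start`,
#'   `strand`, `spacer_class`, `spacer_len`, `heptamer_seq`, `nonamer_seq`,
#'   `heptamer_mm`, `nonamer_mm`, `total_score`.
#' @export
#' @examples
#' seq <- paste0(strrep("T", 30), "CACAGTG", strrep("A", 12), "ACAAAAACC",
#'               strrep("T", 30))
#' scan_rss(seq, spacer_class = "12")
scan_rss <- function(sequence, spacer_class = c("both", "12", "23"),
                     max_heptamer_mm = 3, max_nonamer_mm = 6,
                     require_cac = TRUE,
                     weights = c(heptamer = 2, nonamer = 1),
                     contig = "seq") {
  if (inherits(sequence, "DNAStringSet") || inherits(sequence, "DNAString")) {
    sequence <- as.character(sequence)[1]
  }
  spacer_class <- match.arg(spacer_class)
  .check_dna(sequence)
  cons <- rss_consensus()
  classes <- if (spacer_class == "both") c("12", "23") else spacer_class
  spacer_lens <- sort(unique(unlist(cons$spacer_classes[classes])))
  min_span <- 16L + min(spacer_lens)
  n <- nchar(sequence)
  if (n < min_span) {
    stop("sequence shorter than the minimal RSS span (", min_span, " bp)",
         call. = FALSE)
  }

  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  plus <- .scan_one_strand(chars, spacer_lens, max_heptamer_mm,
                           max_nonamer_mm, require_cac, weights)
  rc_chars <- strsplit(.revcomp(sequence), "", fixed = TRUE)[[1]]
  minus <- .scan_one_strand(rc_chars, spacer_lens, max_heptamer_mm,
                            max_nonamer_mm, require_cac, weights)

  spacer_of <- function(len) {
    ifelse(len %in% cons$spacer_classes$`12`, 12L, 23L)
  }
  rows <- list()
  if (nrow(plus)) {
    rows$plus <- plus |>
      dplyr::mutate(
        strand = "+",
        start = .data$pos0,
        end = .data$pos0 + 16L + .data$spacer_len,
        heptamer_start = .data$pos0
      )
  }
  if (nrow(minus)) {
    # candidate at offset i in the reverse complement occupies plus-strand
    # interval [n - i - span, n - i); its heptamer sits at the right end
    rows$minus <- minus |>
      dplyr::mutate(
        strand = "-",
        end = n - .data$pos0,
        start = .data$end - (16L + .data$spacer_len),
        heptamer_start = .data$end - 7L
      )
  }
  if (!length(rows)) {
    return(.empty_scan())
  }
  res <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      contig = contig,
      spacer_class = spacer_of(.data$spacer_len),
      total_score = as.integer(weights[["heptamer"]] * .data$heptamer_mm +
                                 weights[["nonamer"]] * .data$nonamer_mm)
    )
  # sequences in reading orientation: extract the plus-strand substring of
  # the element, reverse-complementing for minus-strand candidates
  minus_rows <- res$strand == "-"
  hep_plus <- substring(sequence,
                        ifelse(minus_rows, res$end - 6L, res$start + 1L),
                        ifelse(minus_rows, res$end, res$start + 7L))
  non_plus <- substring(sequence,
                        ifelse(minus_rows, res$start + 1L, res$end - 8L),
                        ifelse(minus_rows, res$start + 9L, res$end))
  res$heptamer_seq <- hep_plus
  res$nonamer_seq <- non_plus
  if (any(minus_rows)) {
    res$heptamer_seq[minus_rows] <- .revcomp(hep_plus[minus_rows])
    res$nonamer_seq[minus_rows] <- .revcomp(non_plus[minus_rows])
  }
  res |>
    dplyr::select("contig", "start", "end", "heptamer_start", "strand",
                  "spacer_class", "spacer_len", "heptamer_seq",
                  "nonamer_seq", "heptamer_mm", "nonamer_mm", "total_score") |>
    dplyr::arrange(.data$total_score, .data$heptamer_start, .data$strand)
}

.empty_scan <- function() {
  tibble::tibble(
    contig = character(), start = integer(), end = integer(),
    heptamer_start = integer(), strand = character(),
    spacer_class = integer(), spacer_len = integer(),
    heptamer_seq = character(), nonamer_seq = character(),
    heptamer_mm = integer(), nonamer_mm = integer(), total_score = integer()
  )
}

#' Pair candidate RSSs under the 12/23 rule in deletion-forming orientation
#'
#' The RAG complex joins only RSS pairs with different spacer classes (the
#' 12/23 rule), and a deletion of the intervening DNA requires the two RSSs
#' to face each other across the deleted segment: the left partner on the
#' plus strand (heptamer at the segment's left edge, reading into it) and
#' the right partner on the minus strand (heptamer at the right edge).
#' Both RSS footprints are excised with the deleted segment, so the
#' predicted deletion spans from the plus-strand partner's footprint start
#' to the minus-strand partner's footprint end.
#'
#' @param proximal,distal Candidate tibbles as returned by [scan_rss()]
#'   (typically candidates near the proximal and distal breakpoints).
#' @return A tibble of valid pairs sorted by combined `total_score`, with
#'   prefixed `proximal_*`/`distal_*` candidate columns plus
#'   `deletion_start`, `deletion_end` (0-based half-open) and `pair_score`.
#'   Empty inputs or no compatible pair give an empty tibble.
#' @export
pair_rss <- function(proximal, distal) {
  if (!nrow(proximal) || !nrow(distal)) return(.empty_pairs())
  pairs <- tidyr::crossing(
    pi_ = seq_len(nrow(proximal)),
    di_ = seq_len(nrow(distal))
  )
  p <- proximal[pairs$pi_, ]
  d <- distal[pairs$di_, ]
  ok <- p$spacer_class != d$spacer_class &
    ((p$strand == "+" & d$strand == "-" & p$end <= d$start) |
       (p$strand == "-" & d$strand == "+" & d$end <= p$start))
  if (!any(ok)) return(.empty_pairs())
  p <- p[ok, ]
  d <- d[ok, ]
  left_is_p <- p$strand == "+"
  res <- dplyr::bind_cols(
    dplyr::rename_with(p, ~ paste0("proximal_", .x)),
    dplyr::rename_with(d, ~ paste0("distal_", .x))
  )
  res$deletion_start <- ifelse(left_is_p, p$start, d$start)
  res$deletion_end <- ifelse(left_is_p, d$end, p$end)
  res$pair_score <- p$total_score + d$total_score
  dplyr::arrange(res, .data$pair_score, .data$deletion_start)
}

.empty_pairs <- function() {
  e <- .empty_scan()
  res <- dplyr::bind_cols(
    dplyr::rename_with(e, ~ paste0("proximal_", .x)),
    dplyr::rename_with(e, ~ paste0("distal_", .x))
  )
  res$deletion_start <- integer()
  res$deletion_end <- integer()
  res$pair_score <- integer()
  res
}

#' Annotate breakpoints with the best nearby candidate RSS
#'
#' For each breakpoint position, selects the lowest-scoring candidate whose
#' cleavage edge (the heptamer's outer boundary: `heptamer_start` for a
#' plus-strand candidate, the footprint `end` for a minus-strand one) lies
#' within `window` bp. Ties are broken by distance, then by leftmost
#' position. Breakpoints with no candidate in range are retained with NA
#' candidate columns -- a breakpoint is allowed to have no RSS, as observed
#' for one of the recurrent deletion types.
#'
#' @param candidates Tibble from [scan_rss()].
#' @param breakpoints Integer vector of 0-based breakpoint positions.
#' @param window Maximum distance in bp (default 50, must be > 0).
#' @return A tibble with one row per breakpoint: `breakpoint`, `distance`,
#'   and the matched candidate's columns (NA when none).
#' @export
annotate_breakpoints <- function(candidates, breakpoints, window = 50) {
  stopifnot(window > 0)
  purrr::map_dfr(breakpoints, function(bp) {
    if (!nrow(candidates)) {
      return(tibble::tibble(breakpoint = bp, distance = NA_integer_))
    }
    edge <- ifelse(candidates$strand == "+",
                   candidates$heptamer_start, candidates$end)
    dist <- abs(bp - edge)
    hit <- which(dist <= window)
    if (!length(hit)) {
      return(tibble::tibble(breakpoint = bp, distance = NA_integer_))
    }
    hit <- hit[order(candidates$total_score[hit], dist[hit],
                     candidates$heptamer_start[hit])][1]
    dplyr::bind_cols(
      tibble::tibble(breakpoint = bp, distance = dist[hit]),
      candidates[hit, ]
    )
  })
}
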