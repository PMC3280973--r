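# Independent oracles used to validate the package implementations.
# These deliberately use different code paths (window extraction and
# direct enumeration) than the scanners/statistics they check.

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                               collapse = ""))
}

# naive exhaustive RSS enumerator: extract every heptamer/spacer/nonamer
# window on both strands with substring() and score it directly
oracle_scan <- function(sequence, max_h = 3, max_n = 6, require_cac = TRUE,
                        spacer_lens = c(11:13, 22:24)) {
  cons_h <- "CACAGTG"
  cons_n <- "ACAAAAACC"
  mm <- function(words, cons) {
    k <- nchar(cons)
    tot <- integer(length(words))
    for (j in seq_len(k)) {
      tot <- tot + (substr(words, j, j) != substr(cons, j, j))
    }
    tot
  }
  scan_strand <- function(s) {
    n <- nchar(s)
    out <- list()
    for (sp in spacer_lens) {
      span <- 16L + sp
      if (n < span) next
      i <- seq_len(n - span + 1L)
      hep <- substring(s, i, i + 6L)
      non <- substring(s, i + 7L + sp, i + 15L + sp)
      keep <- mm(hep, cons_h) <= max_h & mm(non, cons_n) <= max_n
      if (require_cac) keep <- keep & substr(hep, 1, 3) == "CAC"
      keep <- keep & !grepl("N", hep, fixed = TRUE) &
        !grepl("N", non, fixed = TRUE)
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          pos0 = i[keep] - 1L, spacer_len = sp,
          heptamer_mm = mm(hep, cons_h)[keep],
          nonamer_mm = mm(non, cons_n)[keep]
        )
      }
    }
    do.call(rbind, c(out, list(data.frame(pos0 = integer(),
                                          spacer_len = integer(),
                                          heptamer_mm = integer(),
                                          nonamer_mm = integer()))))
  }
  n <- nchar(sequence)
  empty <- data.frame(start = integer(), strand = character(),
                      spacer_len = integer(), heptamer_mm = integer(),
                      nonamer_mm = integer())
  plus <- scan_strand(sequence)
  plus <- if (nrow(plus)) {
    plus$strand <- "+"
    plus$start <- plus$pos0
    plus[, names(empty)]
  } else empty
  minus <- scan_strand(oracle_revcomp(sequence))
  minus <- if (nrow(minus)) {
    minus$strand <- "-"
    minus$start <- n - minus$pos0 - (16L + minus$spacer_len)
    minus[, names(empty)]
  } else empty
  res <- rbind(plus, minus)
  res[order(res$start, res$strand, res$spacer_len), , drop = FALSE]
}

# key set for comparing scan outputs regardless of ordering
scan_key <- function(df) {
  sort(paste(df$start, df$strand, df$spacer_len, df$heptamer_mm,
             df$nonamer_mm, sep = ":"))
}

# Fisher's exact two-sided P by direct enumeration of every table with the
# observed margins, using binomial coefficients (no dhyper)
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  p_k <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  sum(p_k[p_k <= p_obs * (1 + 1e-7)])
}

# textbook pooled-variance two-sample t
oracle_student_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  tt <- (mean(x) - mean(y)) / (sp * sqrt(1 / nx + 1 / ny))
  list(t = tt, df = nx + ny - 2,
       p = 2 * pt(abs(tt), nx + ny - 2, lower.tail = FALSE))
}

# exhaustive minimal window containing >= ceil(fraction * n) positions:
# try every pair of positions as window ends
oracle_hotspot <- function(positions, fraction) {
  pos <- sort(positions)
  n <- length(pos)
  k <- ceiling(fraction * n)
  best <- NULL
  for (i in seq_len(n)) {
    for (j in i:n) {
      inside <- sum(pos >= pos[i] & pos <= pos[j])
      if (inside >= k) {
        len <- pos[j] - pos[i] + 1L
        if (is.null(best) || len < best$len ||
            (len == best$len && pos[i] < best$start)) {
          best <- list(len = len, start = pos[i], end = pos[j])
        }
      }
    }
  }
  best
}

# enumerate every (prefix, insertion, distal offset) decomposition that
# reconstructs the junction exactly
oracle_decompositions <- function(junction, prox, dist) {
  n <- nchar(junction)
  out <- list()
  for (p in 0:min(n, nchar(prox))) {
    if (p > 0 && substr(junction, 1, p) != substr(prox, 1, p)) break
    for (s in 0:(n - p)) {
      suffix <- substr(junction, n - s + 1, n)
      mid <- substr(junction, p + 1, n - s)
      hits <- if (s == 0) nchar(dist) + 1 else  # empty suffix: any offset
        gregexpr(suffix, dist, fixed = TRUE)[[1]]
      if (hits[1] > 0) {
        for (h in hits) {
          out[[length(out) + 1L]] <- data.frame(
            proximal_break = p, distal_break = h - 1L, inserted_nt = mid)
        }
      }
    }
  }
  do.call(rbind, out)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Table of the validated breakpoint RSS motifs with mismatch counts
# computed directly (used for embedding-recovery tests)
motif_truth <- function() {
  m <- breakpoint_rss_motifs()
  m <- m[m$has_rss, ]
  m$heptamer_mm <- mismatch_count(m$heptamer, "CACAGTG")
  m$nonamer_mm <- mismatch_count(m$nonamer, "ACAAAAACC")
  m
}
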