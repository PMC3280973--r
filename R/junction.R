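#' Decompose a deletion-spanning junction into breakpoints and insertion
#'
#' Aligns the junction's left end to the start of the proximal reference and
#' its right end into the distal reference, using greedy maximal exact
#' matching: `proximal_break` is the length of the longest junction prefix
#' that matches the proximal reference's prefix, and the distal side is the
#' longest junction suffix occurring in the distal reference. Any unexplained
#' middle is reported as non-templated insertion (N nucleotides added by
#' TdT). When prefix and suffix matches overlap, the overlap is
#' microhomology; the canonical split is taken at the proximal-most
#' position (the overlap is assigned to the distal side) and the insertion
#' is empty.
#'
#' Junctions whose ends fail to anchor with at least `min_anchor` exact
#' bases are flagged rather than raising an error: `status` is `"unrelated"`
#' when neither end anchors (as seen for amplicons that turn out not to
#' derive from the locus) and `"partial_anchor"` when only one end does.
#'
#' @param junction Junction sequence (string).
#' @param proximal_ref Reference sequence whose start aligns with the
#'   junction's start and which extends beyond the breakpoint.
#' @param distal_ref Reference sequence containing the retained distal flank.
#' @param min_anchor Minimum exact match length per side (default 10).
#' @param junction_id Optional identifier carried into the output.
#' @return A one-row tibble: `junction_id`, `status` (`"ok"`,
#'   `"partial_anchor"`, `"unrelated"`), `proximal_break` (0-based offset of
#'   the first proximal base NOT retained), `distal_break` (0-based offset of
#'   the first distal base retained), `inserted_nt`, `microhomology_len`,
#'   `microhomology_seq`. Breakpoint fields are NA unless `status == "ok"`.
#' @export
#' @examples
#' decompose_junction("AAAACCGATTGGCC", "AAAACCTT", "GGTTGGCC", min_anchor = 4)
decompose_junction <- function(junction, proximal_ref, distal_ref,
                               min_anchor = 10, junction_id = NA_character_) {
  stopifnot(nchar(junction) >= 2, nchar(proximal_ref) >= 1,
            nchar(distal_ref) >= 1)
  n <- nchar(junction)

  # longest common prefix of junction and proximal reference
  jp <- strsplit(junction, "", fixed = TRUE)[[1]]
  pp <- strsplit(proximal_ref, "", fixed = TRUE)[[1]]
  lim <- min(n, length(pp))
  neq <- which(jp[seq_len(lim)] != pp[seq_len(lim)])
  p_max <- if (length(neq)) neq[1] - 1L else lim

  # longest junction suffix occurring in the distal reference
  s_max <- 0L
  d_at <- NA_integer_
  for (s in seq(min(n, nchar(distal_ref)), 1L)) {
    hit <- regexpr(substr(junction, n - s + 1L, n), distal_ref,
                   fixed = TRUE)
    if (hit > 0L) {
      s_max <- s
      d_at <- as.integer(hit) - 1L  # 0-based
      break
    }
  }

  anchored_p <- p_max >= min_anchor
  anchored_d <- s_max >= min_anchor
  if (!anchored_p && !anchored_d) {
    return(.junction_row(junction_id, "unrelated"))
  }
  if (!anchored_p || !anchored_d) {
    return(.junction_row(junction_id, "partial_anchor"))
  }

  if (p_max + s_max > n) {
    ov <- p_max + s_max - n
    tibble::tibble(
      junction_id = junction_id, status = "ok",
      proximal_break = n - s_max,
      distal_break = d_at,
      inserted_nt = "",
      microhomology_len = ov,
      microhomology_seq = substr(junction, n - s_max + 1L, p_max)
    )
  } else {
    tibble::tibble(
      junction_id = junction_id, status = "ok",
      proximal_break = p_max,
      distal_break = d_at,
      inserted_nt = substr(junction, p_max + 1L, n - s_max),
      microhomology_len = 0L,
      microhomology_seq = ""
    )
  }
}

.junction_row <- function(junction_id, status) {
  tibble::tibble(
    junction_id = junction_id, status = status,
    proximal_break = NA_integer_, distal_break = NA_integer_,
    inserted_nt = NA_character_, microhomology_len = NA_integer_,
    microhomology_seq = NA_character_
  )
}

#' Decompose a table of junctions
#'
#' Vectorized wrapper around [decompose_junction()]: takes a data frame with
#' one junction per row and returns one call per row.
#'
#' @param data A data frame with columns `junction`, `proximal_ref`,
#'   `distal_ref`, and optionally `junction_id` and `sample_id` (carried
#'   through).
#' @param min_anchor Passed to [decompose_junction()].
#' @return A tibble of junction calls, one row per input row.
#' @export
decompose_junctions <- function(data, min_anchor = 10) {
  stopifnot(all(c("junction", "proximal_ref", "distal_ref") %in% names(data)))
  ids <- if ("junction_id" %in% names(data)) data$junction_id else
    as.character(seq_len(nrow(data)))
  calls <- purrr::pmap_dfr(
    list(data$junction, data$proximal_ref, data$distal_ref, ids),
    function(j, p, d, id) decompose_junction(j, p, d, min_anchor, id)
  )
  if ("sample_id" %in% names(data)) {
    calls <- dplyr::bind_cols(tibble::tibble(sample_id = data$sample_id),
                              calls)
  }
  calls
}

#' Reassemble a junction sequence from a junction call
#'
#' Inverse of [decompose_junction()]; used to verify calls reproduce their
#' input byte-for-byte.
#'
#' @param call One-row tibble as returned by [decompose_junction()] with
#'   `status == "ok"`.
#' @param proximal_ref,distal_ref The references used for decomposition.
#' @param junction_length Total length of the junction to reconstruct.
#' @return The reconstructed junction string.
#' @export
reassemble_junction <- function(call, proximal_ref, distal_ref,
                                junction_length) {
  stopifnot(call$status == "ok")
  dist_len <- junction_length - call$proximal_break - nchar(call$inserted_nt)
  paste0(
    substr(proximal_ref, 1L, call$proximal_break),
    call$inserted_nt,
    substr(distal_ref, call$distal_break + 1L, call$distal_break + dist_len)
  )
}

#' Single-linkage clustering of breakpoint positions
#'
#' Groups positions into clusters in which consecutive members are at most
#' `tolerance` bp apart (single linkage). Clusters are labelled with Roman
#' numerals in order of genomic position, matching the conventional naming
#' of recurrent deletion types.
#'
#' @param positions Integer vector of breakpoint positions (non-empty).
#' @param tolerance Maximum within-cluster gap in bp (default 10).
#' @return A tibble with one row per cluster: `cluster_id`, `representative`
#'   (the rounded median member position), `n_members`, `start`, `end`
#'   (member range, inclusive), and `members` (list column).
#' @export
#' @examples
#' cluster_breakpoints(c(0, 10, 21), tolerance = 10)
cluster_breakpoints <- function(positions, tolerance = 10) {
  if (!length(positions)) stop("`positions` must be non-empty", call. = FALSE)
  pos <- sort(positions)
  breaks <- which(diff(pos) > tolerance)
  grp <- cumsum(c(1L, seq_along(pos)[-1] %in% (breaks + 1L)))
  tibble::tibble(position = pos, grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(
      representative = as.integer(round(stats::median(.data$position))),
      n_members = dplyr::n(),
      start = min(.data$position),
      end = max(.data$position),
      members = list(.data$position),
      .groups = "drop"
    ) |>
    dplyr::mutate(cluster_id = as.character(utils::as.roman(.data$grp))) |>
    dplyr::select("cluster_id", "representative", "n_members", "start",
                  "end", "members")
}

#' Minimal window containing a given fraction of breakpoints
#'
#' Finds the shortest contiguous interval containing at least
#' `ceiling(fraction * n)` of the positions; the hotspot statistic behind
#' statements like "the breakpoints cluster within a region of 33 bp, the
#' majority (75%) within a stretch of 10 bp". Ties are broken by the
#' leftmost start; lengths are inclusive (a single position has length 1).
#'
#' @param positions Integer vector of positions (non-empty).
#' @param fraction Required fraction in (0, 1].
#' @return A one-row tibble: `window_length`, `start`, `end` (inclusive),
#'   `n_inside`, `n_total`.
#' @export
#' @examples
#' hotspot_window(c(5, 6, 7, 8, 100), fraction = 0.8)
hotspot_window <- function(positions, fraction) {
  if (!length(positions)) stop("`positions` must be non-empty", call. = FALSE)
  stopifnot(fraction > 0, fraction <= 1)
  pos <- sort(positions)
  n <- length(pos)
  k <- ceiling(fraction * n)
  # every minimal window starts and ends at a position; slide a k-window
  starts <- pos[seq_len(n - k + 1L)]
  ends <- pos[seq_len(n - k + 1L) + k - 1L]
  lens <- ends - starts + 1L
  i <- which.min(lens)  # which.min takes the first (leftmost) minimum
  tibble::tibble(
    window_length = as.integer(lens[i]),
    start = as.integer(starts[i]),
    end = as.integer(ends[i]),
    n_inside = sum(pos >= starts[i] & pos <= ends[i]),
    n_total = n
  )
}

#' Classify breakpoints against a catalog of recurrent deletion types
#'
#' Assigns each breakpoint the label of the nearest catalog cluster whose
#' representative lies within `tolerance` bp, or `"novel"` otherwise (e.g. a
#' breakpoint 2 kb away from the recurrent hotspot). Equidistant ties go to
#' the lower-position cluster.
#'
#' @param breakpoints Integer vector of breakpoint positions.
#' @param catalog Tibble from [cluster_breakpoints()] (non-empty).
#' @param tolerance Maximum distance to a representative in bp (default 50).
#' @return A tibble: `breakpoint`, `label`, `distance` (NA for `"novel"`).
#' @export
classify_deletion <- function(breakpoints, catalog, tolerance = 50) {
  if (!nrow(catalog)) stop("`catalog` must be non-empty", call. = FALSE)
  cat_ord <- dplyr::arrange(catalog, .data$representative)
  purrr::map_dfr(breakpoints, function(bp) {
    d <- abs(bp - cat_ord$representative)
    i <- which(d == min(d))[1]  # ties resolved to the lower position
    if (d[i] <= tolerance) {
      tibble::tibble(breakpoint = bp, label = cat_ord$cluster_id[i],
                     distance = as.integer(d[i]))
    } else {
      tibble::tibble(breakpoint = bp, label = "novel",
                     distance = NA_integer_)
    }
  })
}

#' Count unique junctions per sample
#'
#' Junctions are unique in their exact breakpoints and interstitial
#' insertion; identical (proximal_break, distal_break, inserted_nt) triples
#' within a sample are one event, and distinct triples count independent
#' subclones that acquired the deletion separately.
#'
#' @param calls Tibble of junction calls with a `sample_id` column.
#' @return A tibble: `sample_id`, `n_unique_junctions`.
#' @export
count_unique_junctions <- function(calls) {
  stopifnot("sample_id" %in% names(calls))
  calls |>
    dplyr::filter(is.na(.data$status) | .data$status == "ok") |>
    dplyr::distinct(.data$sample_id, .data$proximal_break,
                    .data$distal_break, .data$inserted_nt) |>
    dplyr::count(.data$sample_id, name = "n_unique_junctions")
}
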