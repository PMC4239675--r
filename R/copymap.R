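# Mapping copy-number segmentation boundaries to breakends.
#
# Each internal boundary between two adjacent segments with different copy
# values defines a breakpoint interval of length L centered on the boundary.
# A breakend matched to such an interval receives a signed change-in-copy
# value Delta in {-1, 0, +1}: Delta(x) := N(x') - N(x), the copy number on
# the counterpart side minus the copy number on the retained side.  For a
# "+" breakend this equals the left-to-right sign of the boundary; for a
# "-" breakend it is the negated sign.  Magnitudes are collapsed to sign
# because absolute tumor copy number is unreliable.

#' Breakpoint intervals around copy-number segment boundaries
#'
#' One interval per internal boundary at which adjacent segment values
#' differ.  The interval has length `L` and is centered on the midpoint
#' between the left segment's end and the right segment's start; its sign is
#' the sign of (right value - left value).  Boundaries across gaps wider
#' than `max_gap` (copy number undefined in between) and chromosome ends
#' produce no interval.
#'
#' @param segments An [copy_segments()] table (or coercible data.frame).
#' @param L Interval length in bp (default 10000).
#' @param max_gap Largest inter-segment gap still treated as a boundary
#'   (default `L`).
#' @return A data.frame of class `"oa_intervals"`: `chrom`, `center`
#'   (possibly half-integer), `lo`, `hi` (1-based inclusive,
#'   `hi - lo + 1 == L`), `sign` (+1 or -1).
#' @export
boundary_intervals <- function(segments, L = 10000, max_gap = L) {
  stopifnot(L > 0)
  if (!inherits(segments, "oa_segments"))
    segments <- copy_segments(segments$chrom, segments$start, segments$end, segments$value)
  rows <- list()
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    if (nrow(s) < 2L) next
    for (i in seq_len(nrow(s) - 1L)) {
      gap <- s$start[i + 1L] - s$end[i] - 1
      dv <- s$value[i + 1L] - s$value[i]
      if (dv == 0 || gap > max_gap) next
      center <- (s$end[i] + s$start[i + 1L]) / 2
      lo <- floor(center - (L - 1) / 2)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, center = center, lo = lo, hi = lo + L - 1,
        sign = sign(dv), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), center = numeric(0), lo = numeric(0),
               hi = numeric(0), sign = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "L") <- L
  class(out) <- c("oa_intervals", "data.frame")
  out
}

#' Assign change-in-copy values to breakends
#'
#' A breakend matches a breakpoint interval iff it lies within the interval
#' and is the only breakend of the set occupying it; a breakend lying in two
#' overlapping intervals is ambiguous and left unmatched.  Matched breakends
#' receive `Delta = sign` for `"+"` orientation and `Delta = -sign` for
#' `"-"` orientation (the change in copy from the retained side to the
#' counterpart side); all other breakends receive `Delta = 0`.
#'
#' @param x An [adjacencies()] table or breakend data.frame; every breakend
#'   of the analyzed adjacency set must be included, since interval
#'   occupancy is judged against all of them.
#' @param intervals A [boundary_intervals()] table.
#' @return A data.frame of class `"oa_delta"`: `uid`, `chrom`, `pos`,
#'   `orient`, `delta`, `matched`, `interval_center`; attribute `p_delta` is
#'   the fraction of breakends with nonzero `delta`.
#' @export
assign_delta <- function(x, intervals) {
  bk <- .bk_table(x)
  delta <- numeric(nrow(bk))
  matched <- logical(nrow(bk))
  center <- rep(NA_real_, nrow(bk))
  if (nrow(bk) && nrow(intervals)) {
    for (ch in unique(bk$chrom)) {
      iv <- intervals[intervals$chrom == ch, , drop = FALSE]
      if (!nrow(iv)) next
      bi <- which(bk$chrom == ch)
      ## membership matrix: breakend x interval
      inn <- outer(bk$pos[bi], iv$lo, ">=") & outer(bk$pos[bi], iv$hi, "<=")
      n_iv_per_bk <- rowSums(inn)
      n_bk_per_iv <- colSums(inn)
      for (r in seq_along(bi)) {
        if (n_iv_per_bk[r] != 1L) next        # unmatched or ambiguous
        j <- which(inn[r, ])
        if (n_bk_per_iv[j] != 1L) next        # interval not uniquely occupied
        k <- bi[r]
        matched[k] <- TRUE
        center[k] <- iv$center[j]
        delta[k] <- if (bk$orient[k] == "+") iv$sign[j] else -iv$sign[j]
      }
    }
  }
  out <- data.frame(uid = bk$uid, chrom = bk$chrom, pos = bk$pos,
                    orient = bk$orient, delta = delta, matched = matched,
                    interval_center = center, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "p_delta") <- if (nrow(out)) mean(out$delta != 0) else NA_real_
  class(out) <- c("oa_delta", "data.frame")
  out
}
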