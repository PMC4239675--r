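# Counterpart matching and the orientation spectrum of close breakend pairs.
#
# Two observed breakends x (at the lower coordinate) and x' are called
# counterparts when (1) they lie on the same chromosome within distance D,
# (2) they are convergent (x is "+", x' is "-"), (3) the pair {x, x'} is not
# itself a detected adjacency, and (4) no other observed breakend lies
# strictly between them.

.bk_table <- function(x) {
  if (inherits(x, "oa_adjacencies")) oa_breakends(x)
  else if (is.data.frame(x) && all(c("uid", "chrom", "pos", "orient") %in% names(x))) x
  else stop("expected an 'oa_adjacencies' table or a breakend data.frame", call. = FALSE)
}

## coordinate keys of the adjacencies a breakend table came from, used for
## criterion (3); endpoints taken in canonical order
.adjacency_coord_keys <- function(x) {
  if (inherits(x, "oa_adjacencies"))
    return(paste(x$chrom1, x$pos1, x$orient1, x$chrom2, x$pos2, x$orient2, sep = "\r"))
  bk <- .bk_table(x)
  if (is.null(bk$adj_id)) return(character(0))
  keys <- character(0)
  for (id in unique(bk$adj_id)) {
    e <- bk[bk$adj_id == id, , drop = FALSE]
    if (nrow(e) != 2L) next
    first <- .endpoint_first(e$chrom[1], e$pos[1], e$orient[1], e$uid[1],
                             e$chrom[2], e$pos[2], e$orient[2], e$uid[2])
    i <- if (first) 1:2 else 2:1
    keys <- c(keys, paste(e$chrom[i[1]], e$pos[i[1]], e$orient[i[1]],
                          e$chrom[i[2]], e$pos[i[2]], e$orient[i[2]], sep = "\r"))
  }
  keys
}

## All pairs of breakends on one chromosome with no third breakend strictly
## between them: pairs at the same position, or in consecutive distinct
## positions with gap <= D.  `bk` must be sorted by (pos, orient, uid).
## Returns a two-column index matrix into `bk`.
.consecutive_pairs <- function(pos, D) {
  n <- length(pos)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  res <- list()
  grp <- cumsum(c(TRUE, pos[-1L] != pos[-n]))
  idx <- split(seq_len(n), grp)
  ng <- length(idx)
  for (g in seq_len(ng)) {
    ii <- idx[[g]]
    if (length(ii) > 1L) {
      cmb <- t(utils::combn(ii, 2L))
      res[[length(res) + 1L]] <- cmb
    }
    if (g < ng) {
      jj <- idx[[g + 1L]]
      if (pos[jj[1L]] - pos[ii[1L]] <= D)
        res[[length(res) + 1L]] <- as.matrix(expand.grid(ii, jj))
    }
  }
  if (!length(res)) matrix(integer(0), ncol = 2L) else do.call(rbind, res)
}

#' Match breakends into counterpart pairs
#'
#' Identifies pairs of observed breakends that plausibly arose from the same
#' double-stranded break: same chromosome, coordinate distance at most `D`,
#' convergent `(+, -)` orientation, not themselves a detected adjacency, and
#' with no other observed breakend strictly between them.  Each breakend
#' participates in at most one pair; conflicts (only possible when
#' coincident breakends are involved) are resolved greedily, tighter pairs
#' first and then in deterministic coordinate/uid order, which keeps the
#' accepted pairing monotone in `D`.
#'
#' @param x An [adjacencies()] table (matching is performed on its
#'   endpoints) or a breakend data.frame from [oa_breakends()].
#' @param D Distance threshold in bp (default 2000).  Coincident convergent
#'   breakends (distance 0) are accepted.
#' @return A data.frame of class `"oa_pairing"` with columns `uid_plus`,
#'   `uid_minus`, `chrom`, `pos_plus`, `pos_minus`, `distance`, and
#'   attribute `D`.
#' @export
match_counterparts <- function(x, D = 2000) {
  stopifnot(D >= 0)
  bk <- .bk_table(x)
  adj_keys <- .adjacency_coord_keys(x)
  out <- list()
  for (ch in sort(unique(bk$chrom))) {
    b <- bk[bk$chrom == ch, , drop = FALSE]
    b <- b[order(b$pos, .orient_rank(b$orient), b$uid), , drop = FALSE]
    prs <- .consecutive_pairs(b$pos, D)
    if (!nrow(prs)) next
    ## orient the pair as (x, x'): "+" end first
    swap <- b$orient[prs[, 1L]] == "-" & b$orient[prs[, 2L]] == "+" &
      b$pos[prs[, 1L]] == b$pos[prs[, 2L]]
    prs[swap, ] <- prs[swap, 2:1]
    keep <- b$orient[prs[, 1L]] == "+" & b$orient[prs[, 2L]] == "-"
    prs <- prs[keep, , drop = FALSE]
    if (!nrow(prs)) next
    key <- paste(ch, b$pos[prs[, 1L]], "+", ch, b$pos[prs[, 2L]], "-", sep = "\r")
    prs <- prs[!(key %in% adj_keys), , drop = FALSE]
    if (!nrow(prs)) next
    cand <- data.frame(
      uid_plus = b$uid[prs[, 1L]], uid_minus = b$uid[prs[, 2L]],
      chrom = ch, pos_plus = b$pos[prs[, 1L]], pos_minus = b$pos[prs[, 2L]],
      stringsAsFactors = FALSE
    )
    out[[length(out) + 1L]] <- cand
  }
  cand <- if (length(out)) do.call(rbind, out) else
    data.frame(uid_plus = character(0), uid_minus = character(0),
               chrom = character(0), pos_plus = numeric(0), pos_minus = numeric(0),
               stringsAsFactors = FALSE)
  ## greedy one-pair-per-breakend resolution: tighter pairs first (so the
  ## accepted pairing is monotone in D), then deterministic coordinate order
  cand <- cand[order(cand$pos_minus - cand$pos_plus, cand$chrom, cand$pos_plus,
                     cand$uid_plus, cand$uid_minus), , drop = FALSE]
  used <- character(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$uid_plus[i] %in% used) && !(cand$uid_minus[i] %in% used)) {
      keep[i] <- TRUE
      used <- c(used, cand$uid_plus[i], cand$uid_minus[i])
    }
  }
  res <- cand[keep, , drop = FALSE]
  res$distance <- res$pos_minus - res$pos_plus
  rownames(res) <- NULL
  attr(res, "D") <- D
  class(res) <- c("oa_pairing", "data.frame")
  res
}

#' Orientation spectrum of close breakend pairs
#'
#' Counts every pair of breakends on the same chromosome at coordinate
#' distance at most `D` with no other breakend strictly between them,
#' classified by the orientation pattern read in coordinate-sorted order
#' (coincident pairs are read `"+"` first).  Under uniform random
#' orientations each of the four classes has probability 1/4; an excess of
#' the convergent `(+,-)` class signals genuine counterpart pairs.
#'
#' @inheritParams match_counterparts
#' @return A list of class `"oa_spectrum"`: `D`, `counts` (named vector over
#'   `"+-"`, `"-+"`, `"++"`, `"--"`), `total`, `proportions`.
#' @export
orientation_spectrum <- function(x, D = 2000) {
  stopifnot(D >= 0)
  bk <- .bk_table(x)
  classes <- c("+-", "-+", "++", "--")
  counts <- stats::setNames(numeric(4L), classes)
  for (ch in unique(bk$chrom)) {
    b <- bk[bk$chrom == ch, , drop = FALSE]
    b <- b[order(b$pos, .orient_rank(b$orient), b$uid), , drop = FALSE]
    prs <- .consecutive_pairs(b$pos, D)
    if (!nrow(prs)) next
    cls <- paste0(b$orient[prs[, 1L]], b$orient[prs[, 2L]])
    tab <- table(factor(cls, levels = classes))
    counts <- counts + as.numeric(tab)
  }
  total <- sum(counts)
  structure(list(D = D, counts = counts, total = total,
                 proportions = if (total > 0) counts / total else counts * NA_real_),
            class = "oa_spectrum")
}

#' @export
print.oa_spectrum <- function(x, ...) {
  cat(sprintf("orientation spectrum at D = %s bp: %d qualifying pairs\n",
              format(x$D, scientific = FALSE), as.integer(x$total)))
  print(round(x$proportions, 4))
  invisible(x)
}

#' Enrichment of the convergent orientation class
#'
#' One-sided binomial test of the convergent `(+,-)` proportion against the
#' null probability 1/4 expected if orientation pairs were drawn uniformly
#' from the four classes.
#'
#' @param spectrum An [orientation_spectrum()] result with `total > 0`.
#' @param alternative Passed to [stats::binom.test()]; default `"greater"`.
#' @return A list with `proportion`, `p.value`, and the underlying `htest`.
#' @export
convergence_enrichment <- function(spectrum, alternative = "greater") {
  stopifnot(inherits(spectrum, "oa_spectrum"))
  if (spectrum$total == 0)
    stop("orientation spectrum is empty: enrichment is undefined", call. = FALSE)
  ht <- stats::binom.test(as.integer(spectrum$counts[["+-"]]),
                          as.integer(spectrum$total),
                          p = 0.25, alternative = alternative)
  list(proportion = unname(spectrum$proportions[["+-"]]),
       p.value = ht$p.value, test = ht)
}

#' Orientation spectrum over a range of distance thresholds
#'
#' @inheritParams match_counterparts
#' @param D Vector of distance thresholds (bp).
#' @return A data.frame with one row per threshold: `D`, `total`, and the
#'   four class proportions (`p_conv`, `p_div`, `p_pp`, `p_mm`).
#' @export
sweep_orientation_spectrum <- function(x, D = c(1, 32, 100, 316, 1000, 2000,
                                                3162, 10000, 31623, 100000)) {
  rows <- lapply(D, function(d) {
    s <- orientation_spectrum(x, d)
    data.frame(D = d, total = s$total,
               p_conv = s$proportions[["+-"]], p_div = s$proportions[["-+"]],
               p_pp = s$proportions[["++"]], p_mm = s$proportions[["--"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
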