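# k-break rearrangement simulator with ground-truth event labels.
#
# A derivative genome is represented as a collection of threads: linear
# chromosomes (telomeres at both ends) and circular chromosomes, each an
# ordered list of oriented reference segments.  A k-break samples k distinct
# cut sites on the retained derivative, cuts, and fuses the 2k free ends
# according to a uniform perfect matching conditioned on no counterpart
# re-fusion (the break is effective).  Circular products may be lost,
# producing deletions.  Model assumptions: no breakpoint reuse (cut sites
# are distinct across the whole history) and all breakends fused (no new
# telomeres).

.new_thread <- function(chrom, len) {
  list(segs = data.frame(chrom = chrom, start = 1, end = len, dir = 1L,
                         stringsAsFactors = FALSE),
       circular = FALSE, lost = FALSE, dead = FALSE,
       left = list(type = "tel"), right = list(type = "tel"))
}

.thread_len <- function(th) sum(th$segs$end - th$segs$start + 1)

.rev_thread <- function(th) {
  th$segs <- th$segs[rev(seq_len(nrow(th$segs))), , drop = FALSE]
  th$segs$dir <- -th$segs$dir
  rownames(th$segs) <- NULL
  tmp <- th$left; th$left <- th$right; th$right <- tmp
  th
}

.free_end <- function(id, chrom, pos, orient, cut_id)
  list(type = "free", id = id, chrom = chrom, pos = pos, orient = orient,
       cut_id = cut_id)

## Cut thread `th` inside segment row `si`, between reference positions n and
## n+1.  Returns a list of 1 (was circular) or 2 (was linear) threads, with
## the new free ends installed; `next_end_id` supplies end ids.
.cut_thread <- function(th, si, n, cut_id, end_ids) {
  s <- th$segs[si, ]
  if (s$dir == 1L) {
    leftpiece  <- data.frame(chrom = s$chrom, start = s$start, end = n, dir = 1L,
                             stringsAsFactors = FALSE)
    rightpiece <- data.frame(chrom = s$chrom, start = n + 1, end = s$end, dir = 1L,
                             stringsAsFactors = FALSE)
    bk_left  <- c(pos = n, orient = "+")
    bk_right <- c(pos = n + 1, orient = "-")
  } else {
    leftpiece  <- data.frame(chrom = s$chrom, start = n + 1, end = s$end, dir = -1L,
                             stringsAsFactors = FALSE)
    rightpiece <- data.frame(chrom = s$chrom, start = s$start, end = n, dir = -1L,
                             stringsAsFactors = FALSE)
    bk_left  <- c(pos = n + 1, orient = "-")
    bk_right <- c(pos = n, orient = "+")
  }
  end_left  <- .free_end(end_ids[1L], s$chrom, as.numeric(bk_left["pos"]),
                         bk_left[["orient"]], cut_id)
  end_right <- .free_end(end_ids[2L], s$chrom, as.numeric(bk_right["pos"]),
                         bk_right[["orient"]], cut_id)
  m <- nrow(th$segs)
  if (th$circular) {
    ## linearize: rotate so the cut becomes the two ends
    after  <- if (si < m) th$segs[(si + 1L):m, , drop = FALSE] else th$segs[0, ]
    before <- if (si > 1L) th$segs[seq_len(si - 1L), , drop = FALSE] else th$segs[0, ]
    segs <- rbind(rightpiece, after, before, leftpiece)
    rownames(segs) <- NULL
    list(list(segs = segs, circular = FALSE, lost = FALSE, dead = FALSE,
              left = end_right, right = end_left))
  } else {
    segsA <- rbind(if (si > 1L) th$segs[seq_len(si - 1L), , drop = FALSE] else th$segs[0, ],
                   leftpiece)
    segsB <- rbind(rightpiece,
                   if (si < m) th$segs[(si + 1L):m, , drop = FALSE] else th$segs[0, ])
    rownames(segsA) <- rownames(segsB) <- NULL
    list(list(segs = segsA, circular = FALSE, lost = FALSE, dead = FALSE,
              left = th$left, right = end_left),
         list(segs = segsB, circular = FALSE, lost = FALSE, dead = FALSE,
              left = end_right, right = th$right))
  }
}

.find_end <- function(threads, id) {
  for (ti in seq_along(threads)) {
    th <- threads[[ti]]
    if (th$dead || th$circular) next
    if (th$left$type == "free" && th$left$id == id) return(c(ti, 1L))
    if (th$right$type == "free" && th$right$id == id) return(c(ti, 2L))
  }
  stop("internal error: free end not found", call. = FALSE)
}

#' Simulate a k-break rearrangement history
#'
#' Applies a sequence of k-breaks to a reference genome of linear
#' chromosomes.  Each event samples `k` cut sites uniformly over the
#' retained derivative genome (subject to a minimum reference-coordinate
#' spacing between all cut sites, enforcing no breakpoint reuse and keeping
#' breakpoints sparse), cuts, and fuses the `2k` free ends by a uniform
#' perfect matching conditioned on no counterpart re-fusion.  Each circular
#' chromosome produced by an event is lost with probability `circle_loss_p`;
#' a lost circle deletes its content from the derivative genome.
#'
#' @param chrom_lengths Named numeric vector of reference chromosome
#'   lengths (names become chromosome names; `chr1`, `chr2`, ... when
#'   unnamed).
#' @param events Integer vector of `k` values, applied in order (all
#'   `>= 2`).
#' @param circle_loss_p Probability that a newly formed circular chromosome
#'   is lost (default 1, the deletion interpretation).
#' @param min_spacing Minimum distance in bp between any two cut sites on
#'   the same chromosome, across the whole history (default 6000, three
#'   times the default counterpart-matching distance; set to 1 for a
#'   "realistic" mode with no spacing guarantee).
#' @param seed Optional integer seed (`set.seed` is called when supplied).
#' @return A list of class `"kbreak_history"`: `threads` (the derivative
#'   genome), `events` (per-event log: `k`, cut sites), `truth` (one row per
#'   created adjacency: endpoint coordinates, `event`, `event_k`),
#'   `chrom_lengths`, `params`.
#' @export
simulate_history <- function(chrom_lengths, events, circle_loss_p = 1,
                             min_spacing = 6000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  events <- as.integer(events)
  if (length(events) == 0L || any(events < 2L))
    stop("every event must have k >= 2", call. = FALSE)
  stopifnot(circle_loss_p >= 0, circle_loss_p <= 1, min_spacing >= 1)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  total_cuts <- sum(events)
  if (sum(chrom_lengths) < 10 * total_cuts)
    stop("reference too small for the requested number of cuts", call. = FALSE)

  threads <- mapply(.new_thread, names(chrom_lengths), chrom_lengths,
                    SIMPLIFY = FALSE, USE.NAMES = FALSE)
  cuts <- data.frame(chrom = character(0), pos = numeric(0), event = integer(0),
                     stringsAsFactors = FALSE)
  truth <- list()
  ev_log <- list()
  next_end <- 1L

  for (e in seq_along(events)) {
    k <- events[e]
    ## --- place k cuts -----------------------------------------------------
    for (i in seq_len(k)) {
      placed <- FALSE
      for (try in seq_len(10000L)) {
        alive <- which(!vapply(threads, function(t) t$dead || t$lost, logical(1)))
        lens <- vapply(threads[alive], .thread_len, numeric(1))
        ti <- alive[sample.int(length(alive), 1L, prob = lens)]
        th <- threads[[ti]]
        seg_lens <- th$segs$end - th$segs$start + 1
        si <- sample.int(nrow(th$segs), 1L, prob = seg_lens)
        s <- th$segs[si, ]
        if (s$end - s$start < 1) next           # cannot cut a 1-bp segment
        n <- s$start + sample.int(s$end - s$start, 1L) - 1
        prev <- cuts$pos[cuts$chrom == s$chrom]
        if (length(prev) && min(abs(prev - n)) < min_spacing) next
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place cut ", i, " of event ", e,
             " with the requested spacing; enlarge the reference or reduce min_spacing",
             call. = FALSE)
      cuts <- rbind(cuts, data.frame(chrom = s$chrom, pos = n, event = e,
                                     stringsAsFactors = FALSE))
      cut_id <- nrow(cuts)
      pieces <- .cut_thread(th, si, n, cut_id, c(next_end, next_end + 1L))
      next_end <- next_end + 2L
      threads[[ti]]$dead <- TRUE
      threads <- c(threads, pieces)
    }
    threads <- threads[!vapply(threads, `[[`, logical(1), "dead")]

    ## --- sample a fusion matching on the 2k free ends ---------------------
    free_ids <- integer(0)
    ends_info <- list()
    for (th in threads) {
      if (th$lost || th$circular) next
      for (side in c("left", "right")) {
        en <- th[[side]]
        if (en$type == "free") {
          free_ids <- c(free_ids, en$id)
          ends_info[[as.character(en$id)]] <- en
        }
      }
    }
    stopifnot(length(free_ids) == 2L * k)
    repeat {
      perm <- sample(free_ids)
      mt <- matrix(perm, ncol = 2L, byrow = TRUE)
      same_cut <- vapply(seq_len(k), function(r) {
        ends_info[[as.character(mt[r, 1L])]]$cut_id ==
          ends_info[[as.character(mt[r, 2L])]]$cut_id
      }, logical(1))
      if (!any(same_cut)) break
    }

    ## --- apply fusions ----------------------------------------------------
    new_circles <- integer(0)
    for (r in seq_len(k)) {
      ia <- mt[r, 1L]; ib <- mt[r, 2L]
      ea <- ends_info[[as.character(ia)]]; eb <- ends_info[[as.character(ib)]]
      truth[[length(truth) + 1L]] <- data.frame(
        chrom1 = ea$chrom, pos1 = ea$pos, orient1 = ea$orient,
        chrom2 = eb$chrom, pos2 = eb$pos, orient2 = eb$orient,
        event = e, event_k = k, stringsAsFactors = FALSE)
      la <- .find_end(threads, ia)
      lb <- .find_end(threads, ib)
      if (la[1L] == lb[1L]) {                  # both ends of one thread: circle
        th <- threads[[la[1L]]]
        th$circular <- TRUE
        th$left <- list(type = "none"); th$right <- list(type = "none")
        threads[[la[1L]]] <- th
        new_circles <- c(new_circles, la[1L])
      } else {
        TA <- threads[[la[1L]]]
        if (la[2L] == 1L) TA <- .rev_thread(TA)  # end A must be TA's right end
        TB <- threads[[lb[1L]]]
        if (lb[2L] == 2L) TB <- .rev_thread(TB)  # end B must be TB's left end
        merged <- list(segs = rbind(TA$segs, TB$segs), circular = FALSE,
                       lost = FALSE, dead = FALSE, left = TA$left, right = TB$right)
        rownames(merged$segs) <- NULL
        threads[[la[1L]]] <- merged
        threads[[lb[1L]]]$dead <- TRUE
      }
    }
    keep <- !vapply(threads, `[[`, logical(1), "dead")
    ## re-index new_circles before dropping dead threads
    new_circles <- match(new_circles, which(keep))
    new_circles <- new_circles[!is.na(new_circles)]
    threads <- threads[keep]

    ## --- circle loss ------------------------------------------------------
    for (ci in new_circles) {
      if (stats::runif(1L) < circle_loss_p) threads[[ci]]$lost <- TRUE
    }
    ev_log[[e]] <- list(index = e, k = k,
                        cuts = cuts[cuts$event == e, c("chrom", "pos")])
  }

  truth <- do.call(rbind, truth)
  ## canonical endpoint order, matching adjacency canonicalization
  flip <- !.endpoint_first(truth$chrom1, truth$pos1, truth$orient1, NA,
                           truth$chrom2, truth$pos2, truth$orient2, NA)
  if (any(flip)) {
    tmp <- truth[flip, c("chrom1", "pos1", "orient1")]
    truth[flip, c("chrom1", "pos1", "orient1")] <-
      truth[flip, c("chrom2", "pos2", "orient2")]
    truth[flip, c("chrom2", "pos2", "orient2")] <- tmp
  }
  rownames(truth) <- NULL
  structure(list(threads = threads, events = ev_log, truth = truth,
                 cuts = cuts, chrom_lengths = chrom_lengths,
                 params = list(circle_loss_p = circle_loss_p,
                               min_spacing = min_spacing, seed = seed)),
            class = "kbreak_history")
}

#' @export
print.kbreak_history <- function(x, ...) {
  n_circ <- sum(vapply(x$threads, `[[`, logical(1), "circular"))
  n_lost <- sum(vapply(x$threads, `[[`, logical(1), "lost"))
  cat(sprintf(
    "k-break history: %d events (k = %s), %d adjacencies created\n",
    length(x$events), paste(vapply(x$events, `[[`, numeric(1), "k"), collapse = ","),
    nrow(x$truth)))
  cat(sprintf("derivative genome: %d linear chromosomes, %d circles (%d lost)\n",
              length(x$threads) - n_circ, n_circ, n_lost))
  invisible(x)
}

## breakend at the thread-order right end of a segment row
.seg_right_bk <- function(s) {
  if (s$dir == 1L) list(chrom = s$chrom, pos = s$end, orient = "+")
  else list(chrom = s$chrom, pos = s$start, orient = "-")
}
## breakend at the thread-order left end of a segment row
.seg_left_bk <- function(s) {
  if (s$dir == 1L) list(chrom = s$chrom, pos = s$start, orient = "-")
  else list(chrom = s$chrom, pos = s$end, orient = "+")
}

.ref_contiguous <- function(s1, s2) {
  s1$chrom == s2$chrom && s1$dir == s2$dir &&
    ((s1$dir == 1L && s2$start == s1$end + 1) ||
     (s1$dir == -1L && s2$end == s1$start - 1))
}

## enumerate novel junctions on retained threads
.derivative_junctions <- function(history) {
  rows <- list()
  for (th in history$threads) {
    if (th$lost) next
    m <- nrow(th$segs)
    jpairs <- if (m > 1L) cbind(seq_len(m - 1L), 2:m) else NULL
    if (th$circular) jpairs <- rbind(jpairs, c(m, 1L))
    if (is.null(jpairs)) next
    for (r in seq_len(nrow(jpairs))) {
      s1 <- th$segs[jpairs[r, 1L], ]
      s2 <- th$segs[jpairs[r, 2L], ]
      if (.ref_contiguous(s1, s2)) next       # restored reference adjacency
      b1 <- .seg_right_bk(s1); b2 <- .seg_left_bk(s2)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom1 = b1$chrom, pos1 = b1$pos, orient1 = b1$orient,
        chrom2 = b2$chrom, pos2 = b2$pos, orient2 = b2$orient,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(chrom1 = character(0), pos1 = numeric(0), orient1 = character(0),
                      chrom2 = character(0), pos2 = numeric(0), orient2 = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

## true copy profile by base-coverage counting of retained segments
.coverage_segments <- function(history, baseline_copy = 1) {
  rows <- list()
  for (ch in names(history$chrom_lengths)) {
    len <- history$chrom_lengths[[ch]]
    starts <- numeric(0); ends <- numeric(0)
    for (th in history$threads) {
      if (th$lost) next
      s <- th$segs[th$segs$chrom == ch, , drop = FALSE]
      starts <- c(starts, s$start); ends <- c(ends, s$end)
    }
    brk <- sort(unique(c(1, starts, ends + 1, len + 1)))
    brk <- brk[brk >= 1 & brk <= len + 1]
    ev <- numeric(length(brk))
    ev <- ev + vapply(brk, function(b) sum(starts == b) - sum(ends + 1 == b), numeric(1))
    cov <- cumsum(ev)
    seg_start <- brk[-length(brk)]
    seg_end <- brk[-1L] - 1
    val <- cov[-length(cov)] + baseline_copy
    ## merge runs of equal value (runs are contiguous in coordinate order)
    keep <- c(TRUE, val[-1L] != val[-length(val)])
    idx <- which(keep)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ch,
      start = seg_start[idx],
      end = c(seg_start[idx[-1L]] - 1, seg_end[length(seg_end)]),
      value = val[idx],
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  copy_segments(df$chrom, df$start, df$end, df$value)
}

#' Derive an observed dataset from a simulated history
#'
#' Collects the novel adjacencies present on retained derivative
#' chromosomes, labels each with its generating event, then applies the
#' observation noise model: independent detection dropout and integer
#' Gaussian positional jitter (clipped to three standard deviations, never
#' flipping orientation).  The true copy profile is derived by base-coverage
#' counting of retained segments over a constant homologue baseline.
#'
#' @param history A [simulate_history()] result.
#' @param dropout_p Probability that a surviving adjacency goes undetected
#'   (default 0).
#' @param jitter_sd Standard deviation (bp) of positional jitter (default 0,
#'   exact positions).
#' @param set_id Name for the resulting adjacency set.
#' @param baseline_copy Copy number contributed by the unrearranged
#'   homologue(s) (default 1, so single-copy losses read 2 to 1).
#' @param seed Optional integer seed.
#' @return A list of class `"oa_sim"`: `adjacencies` (an [adjacencies()]
#'   table with truth columns `event`, `event_k`), `segments` (a
#'   [copy_segments()] table), `truth_fraction` (post-dropout fraction of
#'   adjacencies from (k>2)-breaks; `NA` when nothing was observed),
#'   `params`.
#' @export
observe <- function(history, dropout_p = 0, jitter_sd = 0, set_id = "sim",
                    baseline_copy = 1, seed = NULL) {
  stopifnot(inherits(history, "kbreak_history"), dropout_p >= 0, dropout_p < 1,
            jitter_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  jn <- .derivative_junctions(history)
  ## canonicalize endpoint order before truth lookup
  if (nrow(jn)) {
    flip <- !.endpoint_first(jn$chrom1, jn$pos1, jn$orient1, NA,
                             jn$chrom2, jn$pos2, jn$orient2, NA)
    if (any(flip)) {
      tmp <- jn[flip, c("chrom1", "pos1", "orient1")]
      jn[flip, c("chrom1", "pos1", "orient1")] <- jn[flip, c("chrom2", "pos2", "orient2")]
      jn[flip, c("chrom2", "pos2", "orient2")] <- tmp
    }
    key <- function(d) paste(d$chrom1, d$pos1, d$orient1,
                             d$chrom2, d$pos2, d$orient2, sep = "\r")
    hit <- match(key(jn), key(history$truth))
    if (anyNA(hit))
      stop("internal error: derivative junction without a truth record", call. = FALSE)
    jn$event <- history$truth$event[hit]
    jn$event_k <- history$truth$event_k[hit]
  } else {
    jn$event <- integer(0); jn$event_k <- integer(0)
  }
  ## detection dropout
  if (nrow(jn) && dropout_p > 0)
    jn <- jn[stats::runif(nrow(jn)) >= dropout_p, , drop = FALSE]
  ## positional jitter
  if (nrow(jn) && jitter_sd > 0) {
    lens <- history$chrom_lengths
    jit <- function(pos, chrom) {
      z <- round(pmin(pmax(stats::rnorm(length(pos), 0, jitter_sd),
                           -3 * jitter_sd), 3 * jitter_sd))
      pmin(pmax(pos + z, 1), as.numeric(lens[chrom]))
    }
    jn$pos1 <- jit(jn$pos1, jn$chrom1)
    jn$pos2 <- jit(jn$pos2, jn$chrom2)
  }
  adj <- if (nrow(jn)) {
    n <- nrow(jn)
    adjacencies(jn$chrom1, jn$pos1, jn$orient1, jn$chrom2, jn$pos2, jn$orient2,
                set_id = set_id, event = jn$event, event_k = jn$event_k,
                uid1 = sprintf("%s_b%d", set_id, 2L * seq_len(n) - 1L),
                uid2 = sprintf("%s_b%d", set_id, 2L * seq_len(n)))
  } else {
    adjacencies(character(0), numeric(0), character(0),
                character(0), numeric(0), character(0), set_id = character(0))
  }
  structure(list(
    adjacencies = adj,
    segments = .coverage_segments(history, baseline_copy),
    truth_fraction = if (nrow(jn)) mean(jn$event_k > 2) else NA_real_,
    params = list(dropout_p = dropout_p, jitter_sd = jitter_sd,
                  baseline_copy = baseline_copy, set_id = set_id, seed = seed)),
    class = "oa_sim")
}

#' @export
print.oa_sim <- function(x, ...) {
  cat(sprintf("simulated observation: %d adjacencies, %d copy segments, truth (k>2) fraction %s\n",
              nrow(x$adjacencies), nrow(x$segments),
              format(x$truth_fraction, digits = 3)))
  invisible(x)
}

#' Bernoulli cohort of change-in-copy endpoint pairs
#'
#' Generates the idealized cohort underlying the CAE derivation: `n_adj`
#' adjacencies whose endpoint Delta values are restricted to `{-1, 0}`.  A
#' `frac_k` share (the (k>2)-break adjacencies) receives independent
#' endpoint values with `P(Delta != 0) = p_delta`; the rest (2-break
#' adjacencies) receive equal endpoint values, nonzero with probability
#' `p_delta`.
#'
#' @param n_adj Number of adjacencies.
#' @param frac_k Fraction of adjacencies from (k>2)-breaks, in `[0, 1]`
#'   (realized as `round(frac_k * n_adj)` adjacencies).
#' @param p_delta Probability of a nonzero endpoint Delta, in `(0, 1)`.
#' @param seed Optional integer seed.
#' @return A data.frame with columns `delta_x`, `delta_y`, `is_k`;
#'   attribute `truth_fraction` is the realized (k>2)-break share.
#' @export
bernoulli_cohort <- function(n_adj, frac_k, p_delta, seed = NULL) {
  stopifnot(n_adj >= 1, frac_k >= 0, frac_k <= 1, p_delta > 0, p_delta < 1)
  if (!is.null(seed)) set.seed(seed)
  n_k <- round(frac_k * n_adj)
  is_k <- c(rep(TRUE, n_k), rep(FALSE, n_adj - n_k))
  dx <- numeric(n_adj); dy <- numeric(n_adj)
  if (n_k > 0) {
    dx[is_k] <- -stats::rbinom(n_k, 1L, p_delta)
    dy[is_k] <- -stats::rbinom(n_k, 1L, p_delta)
  }
  if (n_adj - n_k > 0) {
    shared <- -stats::rbinom(n_adj - n_k, 1L, p_delta)
    dx[!is_k] <- shared
    dy[!is_k] <- shared
  }
  out <- data.frame(delta_x = dx, delta_y = dy, is_k = is_k)
  attr(out, "truth_fraction") <- n_k / n_adj
  out
}

#' CAE of a Bernoulli cohort
#'
#' Convenience wrapper: computes the empirical `p_delta` over all endpoint
#' values of the cohort and applies [cae()] to the copy-asymmetric count.
#'
#' @param cohort A [bernoulli_cohort()] result.
#' @return The CAE value (`NA` with a warning when the empirical `p_delta`
#'   is 0 or 1).
#' @export
cae_bernoulli <- function(cohort) {
  calls <- data.frame(set_id = "bernoulli", adj_id = seq_len(nrow(cohort)),
                      counterpart_asym = FALSE,
                      copy_asym = cohort$delta_x != cohort$delta_y,
                      open = cohort$delta_x != cohort$delta_y,
                      stringsAsFactors = FALSE)
  p_hat <- mean(c(cohort$delta_x, cohort$delta_y) != 0)
  cae(calls, p_hat)
}
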