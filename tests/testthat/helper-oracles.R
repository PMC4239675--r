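# Independent brute-force oracles and random-instance generators used by the
# property-style suites.

## Brute-force counterpart matcher: literal all-pairs application of the four
## criteria, then the same greedy (distance-first) conflict resolution as the
## package.  Kept independent of the sorted-scan implementation.
brute_match <- function(adj, D) {
  bk <- oa_breakends(adj)
  ## adjacency coordinate keys (canonical endpoint order)
  adj_keys <- paste(adj$chrom1, adj$pos1, adj$orient1,
                    adj$chrom2, adj$pos2, adj$orient2, sep = "\r")
  n <- nrow(bk)
  cand <- list()
  plus <- which(bk$orient == "+")
  minus <- which(bk$orient == "-")
  for (i in plus) {
    for (j in minus) {
      if (bk$chrom[i] != bk$chrom[j]) next
      d <- bk$pos[j] - bk$pos[i]
      if (d < 0 || d > D) next                                  # criterion 1 (+2 by loop)
      if (any(bk$chrom == bk$chrom[i] &
              bk$pos > bk$pos[i] & bk$pos < bk$pos[j])) next    # criterion 4
      key <- paste(bk$chrom[i], bk$pos[i], "+",
                   bk$chrom[j], bk$pos[j], "-", sep = "\r")
      if (key %in% adj_keys) next                               # criterion 3
      cand[[length(cand) + 1L]] <- data.frame(
        uid_plus = bk$uid[i], uid_minus = bk$uid[j], chrom = bk$chrom[i],
        pos_plus = bk$pos[i], pos_minus = bk$pos[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(cand))
    return(data.frame(uid_plus = character(0), uid_minus = character(0),
                      chrom = character(0), pos_plus = numeric(0),
                      pos_minus = numeric(0), distance = numeric(0),
                      stringsAsFactors = FALSE))
  cand <- do.call(rbind, cand)
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
  out <- cand[keep, , drop = FALSE]
  out$distance <- out$pos_minus - out$pos_plus
  rownames(out) <- NULL
  out
}

## Brute-force interval-membership Delta assignment.
brute_delta <- function(adj, intervals) {
  bk <- oa_breakends(adj)
  delta <- numeric(nrow(bk))
  for (i in seq_len(nrow(bk))) {
    hit <- which(intervals$chrom == bk$chrom[i] &
                 intervals$lo <= bk$pos[i] & intervals$hi >= bk$pos[i])
    if (length(hit) != 1L) next
    occupants <- sum(bk$chrom == bk$chrom[i] &
                     bk$pos >= intervals$lo[hit] & bk$pos <= intervals$hi[hit])
    if (occupants != 1L) next
    delta[i] <- if (bk$orient[i] == "+") intervals$sign[hit] else -intervals$sign[hit]
  }
  data.frame(uid = bk$uid, delta = delta, stringsAsFactors = FALSE)
}

## Random adjacency set: n breakends at random positions/orientations paired
## randomly into adjacencies.  Coincident breakends are legal.
random_instance <- function(n_breakends = 50, n_chrom = 2, span = 50000) {
  n <- 2L * (n_breakends %/% 2L)
  chrom <- sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE)
  pos <- sample.int(span, n, replace = TRUE)
  orient <- sample(c("+", "-"), n, replace = TRUE)
  idx <- matrix(sample.int(n), ncol = 2L)
  adjacencies(chrom[idx[, 1]], pos[idx[, 1]], orient[idx[, 1]],
              chrom[idx[, 2]], pos[idx[, 2]], orient[idx[, 2]])
}

## Random segmentation: a few integer-valued segments per chromosome.
random_segmentation <- function(n_chrom = 2, span = 50000, n_seg = 5) {
  rows <- list()
  for (c_i in seq_len(n_chrom)) {
    cuts <- sort(sample.int(span - 1L, n_seg - 1L))
    start <- c(1, cuts + 1)
    end <- c(cuts, span)
    value <- sample.int(4L, n_seg, replace = TRUE)
    rows[[c_i]] <- data.frame(chrom = paste0("chr", c_i), start = start,
                              end = end, value = value, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  copy_segments(df$chrom, df$start, df$end, df$value)
}

## Simulate, observe exactly, and run the classification pipeline; returns
## the observation plus per-adjacency calls aligned with truth labels.
sim_and_classify <- function(events, chrom_lengths = c(chrA = 1.5e6, chrB = 1.5e6),
                             seed = 1, D = 2000, L = 10000) {
  h <- simulate_history(chrom_lengths, events, circle_loss_p = 1, seed = seed)
  ob <- observe(h)
  adj <- ob$adjacencies
  pairing <- match_counterparts(adj, D)
  delta <- if (nrow(adj)) assign_delta(adj, boundary_intervals(ob$segments, L)) else NULL
  calls <- if (nrow(adj)) classify_adjacencies(adj, pairing, delta) else NULL
  list(history = h, observation = ob, adj = adj, pairing = pairing,
       delta = delta, calls = calls)
}
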