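#' @keywords internal
"_PACKAGE"

# Orientation convention used throughout: a double-stranded break between
# nucleotides n and n+1 (1-based) produces the counterpart breakends
# (n, "+") and (n+1, "-").  "+" means the breakend retains the
# lower-coordinate side of the break; "-" the higher-coordinate side.

ORIENTS <- c("+", "-")

## orientation rank used for canonical ordering: "+" sorts before "-"
.orient_rank <- function(orient) match(orient, ORIENTS)

.check_orient <- function(orient) {
  if (!all(orient %in% ORIENTS))
    stop("orientation must be one of \"+\", \"-\"", call. = FALSE)
  orient
}

.check_pos <- function(pos) {
  if (any(is.na(pos)) || any(pos < 1) || any(pos != round(pos)))
    stop("breakend positions must be integers >= 1", call. = FALSE)
  as.numeric(pos)
}

#' Construct a breakend
#'
#' A breakend is an oriented genomic position representing one side of a
#' double-stranded DNA break.  Positions are 1-based nucleotide indices; a
#' break between nucleotides `n` and `n + 1` yields the counterpart pair
#' `(n, "+")` and `(n + 1, "-")`.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based genomic coordinate (integer, `>= 1`).
#' @param orient `"+"` if the breakend retains the lower-coordinate side of
#'   the break, `"-"` otherwise.
#' @param uid Identifier unique within a dataset; distinguishes coincident
#'   breakends originating from different adjacencies.
#' @return A list of class `"oa_breakend"` with elements `chrom`, `pos`,
#'   `orient`, `uid`.
#' @examples
#' breakend("chr17", 105227, "+")
#' @export
breakend <- function(chrom, pos, orient, uid = NA_character_) {
  stopifnot(length(chrom) == 1L, length(pos) == 1L, length(orient) == 1L)
  structure(
    list(chrom = as.character(chrom), pos = .check_pos(pos),
         orient = .check_orient(orient), uid = as.character(uid)),
    class = "oa_breakend"
  )
}

#' @export
print.oa_breakend <- function(x, ...) {
  cat(sprintf("breakend (%s:%s, %s)%s\n", x$chrom, format(x$pos, scientific = FALSE),
              x$orient, if (is.na(x$uid)) "" else paste0(" [", x$uid, "]")))
  invisible(x)
}

#' Ideal counterpart of a breakend
#'
#' Returns the position and orientation of the counterpart breakend that the
#' same break would have produced: a break between nucleotides `n` and
#' `n + 1` yields `(n, "+")` and `(n + 1, "-")`, so the counterpart of
#' `(n, "+")` is `(n + 1, "-")` and vice versa.  Applying the function twice
#' returns the original breakend (up to `uid`).
#'
#' @param x A [breakend()].
#' @return A breakend template (class `"oa_breakend"`, `uid` is `NA`).
#' @examples
#' counterpart_position(breakend("chr1", 105227, "+"))
#' @export
counterpart_position <- function(x) {
  stopifnot(inherits(x, "oa_breakend"))
  if (x$orient == "+") {
    breakend(x$chrom, x$pos + 1, "-")
  } else {
    if (x$pos - 1 < 1)
      stop("counterpart position would fall below coordinate 1", call. = FALSE)
    breakend(x$chrom, x$pos - 1, "+")
  }
}

## Canonical endpoint order for an adjacency: (chrom, pos, orient "+"<"-", uid).
## Returns TRUE where endpoint 1 should come first.
.endpoint_first <- function(chrom1, pos1, orient1, uid1, chrom2, pos2, orient2, uid2) {
  o1 <- .orient_rank(orient1); o2 <- .orient_rank(orient2)
  u1 <- as.character(uid1); u2 <- as.character(uid2)
  ifelse(chrom1 != chrom2, chrom1 < chrom2,
  ifelse(pos1 != pos2, pos1 < pos2,
  ifelse(o1 != o2, o1 < o2,
         !is.na(u1) & !is.na(u2) & u1 <= u2)))
}

#' Build a table of adjacencies
#'
#' An adjacency is an unordered pair of breakends fused together in the
#' derivative (tumor) genome.  Endpoints are stored in canonical order
#' (chromosome, position, then `"+"` before `"-"`, then uid), so equality is
#' independent of input order.
#'
#' @param chrom1,pos1,orient1 First endpoint (vectors, recycled per row).
#' @param chrom2,pos2,orient2 Second endpoint.
#' @param set_id Name of the adjacency set each row belongs to.
#' @param uid1,uid2 Optional breakend identifiers; generated (`"b1"`,
#'   `"b2"`, ...) when missing.  Must be unique across all endpoints.
#' @param event,event_k Optional truth annotation (simulation only): index of
#'   the generating k-break and its `k`.
#' @return A `data.frame` of class `"oa_adjacencies"` with columns `set_id`,
#'   `adj_id`, `chrom1`, `pos1`, `orient1`, `uid1`, `chrom2`, `pos2`,
#'   `orient2`, `uid2`, `event`, `event_k`.
#' @examples
#' adjacencies("chr2", 500, "-", "chr1", 100, "+")
#' @export
adjacencies <- function(chrom1, pos1, orient1, chrom2, pos2, orient2,
                        set_id = "set1", uid1 = NULL, uid2 = NULL,
                        event = NA_integer_, event_k = NA_integer_) {
  n <- length(pos1)
  df <- data.frame(
    set_id = rep_len(as.character(set_id), n),
    adj_id = seq_len(n),
    chrom1 = rep_len(as.character(chrom1), n),
    pos1 = .check_pos(rep_len(pos1, n)),
    orient1 = .check_orient(rep_len(as.character(orient1), n)),
    uid1 = if (is.null(uid1)) sprintf("b%d", 2L * seq_len(n) - 1L)
           else rep_len(as.character(uid1), n),
    chrom2 = rep_len(as.character(chrom2), n),
    pos2 = .check_pos(rep_len(pos2, n)),
    orient2 = .check_orient(rep_len(as.character(orient2), n)),
    uid2 = if (is.null(uid2)) sprintf("b%d", 2L * seq_len(n))
           else rep_len(as.character(uid2), n),
    event = rep_len(as.integer(event), n),
    event_k = rep_len(as.integer(event_k), n),
    stringsAsFactors = FALSE
  )
  as_adjacencies(df)
}

#' Coerce and canonicalize an adjacency table
#'
#' Validates uid uniqueness, forbids self-adjacencies, and enforces the
#' canonical endpoint order on every row.
#'
#' @param df A data.frame with the columns produced by [adjacencies()]
#'   (`event`/`event_k` optional).
#' @return A canonicalized `data.frame` of class `"oa_adjacencies"`.
#' @export
as_adjacencies <- function(df) {
  req <- c("set_id", "chrom1", "pos1", "orient1", "uid1",
           "chrom2", "pos2", "orient2", "uid2")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing adjacency columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(df$adj_id)) df$adj_id <- seq_len(nrow(df))
  if (is.null(df$event)) df$event <- NA_integer_
  if (is.null(df$event_k)) df$event_k <- NA_integer_
  if (nrow(df)) {
    if (any(df$uid1 == df$uid2))
      stop("self-adjacency: the two endpoints of an adjacency must have distinct uids",
           call. = FALSE)
    uids <- c(df$uid1, df$uid2)
    if (anyDuplicated(uids))
      stop("breakend uids must be unique across all adjacency endpoints; duplicated: ",
           paste(unique(uids[duplicated(uids)]), collapse = ", "), call. = FALSE)
    flip <- !.endpoint_first(df$chrom1, df$pos1, df$orient1, df$uid1,
                             df$chrom2, df$pos2, df$orient2, df$uid2)
    if (any(flip)) {
      tmp <- df[flip, c("chrom1", "pos1", "orient1", "uid1")]
      df[flip, c("chrom1", "pos1", "orient1", "uid1")] <-
        df[flip, c("chrom2", "pos2", "orient2", "uid2")]
      df[flip, c("chrom2", "pos2", "orient2", "uid2")] <- tmp
    }
  }
  df <- df[c("set_id", "adj_id", req[-1], "event", "event_k")]
  rownames(df) <- NULL
  class(df) <- c("oa_adjacencies", "data.frame")
  df
}

#' Canonical unordered adjacency from two breakends
#'
#' @param x,y [breakend()]s with distinct uids.
#' @param set_id Adjacency set name.
#' @return A one-row `"oa_adjacencies"` table; `canonical_adjacency(x, y)`
#'   and `canonical_adjacency(y, x)` are identical.
#' @examples
#' canonical_adjacency(breakend("chr2", 500, "-", "u1"),
#'                     breakend("chr1", 100, "+", "u2"))
#' @export
canonical_adjacency <- function(x, y, set_id = "set1") {
  stopifnot(inherits(x, "oa_breakend"), inherits(y, "oa_breakend"))
  ux <- if (is.na(x$uid)) "b1" else x$uid
  uy <- if (is.na(y$uid)) "b2" else y$uid
  if (identical(ux, uy))
    stop("self-adjacency: breakends share uid \"", ux, "\"", call. = FALSE)
  adjacencies(x$chrom, x$pos, x$orient, y$chrom, y$pos, y$orient,
              set_id = set_id, uid1 = ux, uid2 = uy)
}

#' Long (one row per breakend) view of an adjacency table
#'
#' @param adj An `"oa_adjacencies"` table.
#' @return A data.frame with columns `uid`, `chrom`, `pos`, `orient`,
#'   `adj_id`, `set_id`, two rows per adjacency.
#' @export
oa_breakends <- function(adj) {
  stopifnot(is.data.frame(adj))
  out <- data.frame(
    uid = c(adj$uid1, adj$uid2),
    chrom = c(adj$chrom1, adj$chrom2),
    pos = c(adj$pos1, adj$pos2),
    orient = c(adj$orient1, adj$orient2),
    adj_id = c(adj$adj_id, adj$adj_id),
    set_id = c(adj$set_id, adj$set_id),
    stringsAsFactors = FALSE
  )
  out[order(out$chrom, out$pos, .orient_rank(out$orient), out$uid), , drop = FALSE]
}

#' Validate a copy-number segmentation table
#'
#' Segments are 1-based, inclusive, non-overlapping and sorted within each
#' chromosome.  `value` is the copy number; the absolute scale is irrelevant
#' downstream (only differences across segment boundaries are used).
#'
#' @param chrom,start,end,value Segment columns (vectors, one per segment).
#' @return A `data.frame` of class `"oa_segments"`.
#' @export
copy_segments <- function(chrom, start, end, value) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start < 1) || any(df$end < df$start))
      stop("segments must satisfy 1 <= start <= end", call. = FALSE)
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    for (ch in unique(df$chrom)) {
      s <- df[df$chrom == ch, , drop = FALSE]
      if (nrow(s) > 1L) {
        bad <- which(s$start[-1L] <= s$end[-nrow(s)])
        if (length(bad))
          stop(sprintf(
            "overlapping segments on %s: [%d,%d] and [%d,%d]", ch,
            s$start[bad[1L]], s$end[bad[1L]], s$start[bad[1L] + 1L], s$end[bad[1L] + 1L]),
            call. = FALSE)
      }
    }
  }
  rownames(df) <- NULL
  class(df) <- c("oa_segments", "data.frame")
  df
}
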