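# Readers and writers for the on-disk formats.
#
# BEDPE is the canonical adjacency format.  On disk BEDPE is 0-based,
# half-open; internally positions are 1-based nucleotide indices.  Each
# breakend is the 1-bp interval of its side, and its internal position is
# the interval's end coordinate (the last retained base); strand1/strand2
# map directly to breakend orientations.  A minimal TSV dialect
# (chrom1, pos1, orient1, chrom2, pos2, orient2, set_id) is also supported.

.read_lines_table <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln) & nzchar(trimws(ln))]
  ln
}

## parse the BEDPE name column: "setid" or "setid|ev<event>|k<k>"
.parse_name <- function(name) {
  name[name == "." | !nzchar(name)] <- "set1"
  parts <- strsplit(name, "|", fixed = TRUE)
  set_id <- vapply(parts, `[[`, character(1), 1L)
  event <- rep(NA_integer_, length(name))
  event_k <- rep(NA_integer_, length(name))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    ev <- grep("^ev[0-9]+$", p, value = TRUE)
    kk <- grep("^k[0-9]+$", p, value = TRUE)
    if (length(ev)) event[i] <- as.integer(sub("^ev", "", ev[1L]))
    if (length(kk)) event_k[i] <- as.integer(sub("^k", "", kk[1L]))
  }
  list(set_id = set_id, event = event, event_k = event_k)
}

#' Read adjacencies from a BEDPE file
#'
#' Accepts standard 10+-column BEDPE (`chrom1 start1 end1 chrom2 start2 end2
#' name score strand1 strand2`) or the 8-column dialect without name/score.
#' 0-based half-open intervals are converted to internal 1-based breakend
#' positions (the end coordinate of each side); strands become orientations.
#' The name column supplies the adjacency set id, optionally with a
#' simulation truth annotation (`setid|ev<event>|k<k>`).
#'
#' @param path File path.
#' @return An [adjacencies()] table (possibly several sets).
#' @export
read_bedpe <- function(path) {
  ln <- .read_lines_table(path)
  if (!length(ln))
    return(adjacencies(character(0), numeric(0), character(0),
                       character(0), numeric(0), character(0), set_id = character(0)))
  fields <- strsplit(ln, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 8L & nf < 10L))
    stop("malformed BEDPE line ", which(nf != 8L & nf < 10L)[1L],
         ": expected 8 or >= 10 tab-separated columns", call. = FALSE)
  get <- function(i) vapply(fields, `[[`, character(1), i)
  eight <- nf[1L] == 8L
  if (any((nf == 8L) != eight))
    stop("BEDPE mixes 8-column and 10-column records", call. = FALSE)
  chrom1 <- get(1L); chrom2 <- get(4L)
  end1 <- suppressWarnings(as.numeric(get(3L)))
  end2 <- suppressWarnings(as.numeric(get(6L)))
  if (anyNA(end1) || anyNA(end2))
    stop("malformed BEDPE line ", which(is.na(end1) | is.na(end2))[1L],
         ": non-numeric coordinates", call. = FALSE)
  if (eight) {
    strand1 <- get(7L); strand2 <- get(8L)
    nm <- list(set_id = rep("set1", length(ln)),
               event = NA_integer_, event_k = NA_integer_)
  } else {
    strand1 <- get(9L); strand2 <- get(10L)
    nm <- .parse_name(get(7L))
  }
  bad <- which(!(strand1 %in% ORIENTS) | !(strand2 %in% ORIENTS))
  if (length(bad))
    stop("malformed BEDPE line ", bad[1L], ": unknown strand symbol \"",
         setdiff(c(strand1[bad], strand2[bad]), ORIENTS)[1L], "\"", call. = FALSE)
  adjacencies(chrom1, end1, strand1, chrom2, end2, strand2,
              set_id = nm$set_id, event = nm$event, event_k = nm$event_k)
}

#' Write adjacencies to a BEDPE file
#'
#' Inverse of [read_bedpe()]: each breakend becomes the 1-bp interval
#' `[pos - 1, pos)` in 0-based half-open coordinates.  The name column
#' carries the set id, with `|ev<event>|k<k>` appended for rows that carry a
#' simulation truth annotation.
#'
#' @param adj An [adjacencies()] table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(adj, path) {
  name <- adj$set_id
  has_truth <- !is.na(adj$event) & !is.na(adj$event_k)
  name[has_truth] <- sprintf("%s|ev%d|k%d", adj$set_id[has_truth],
                             adj$event[has_truth], adj$event_k[has_truth])
  df <- data.frame(adj$chrom1, format(adj$pos1 - 1, scientific = FALSE, trim = TRUE),
                   format(adj$pos1, scientific = FALSE, trim = TRUE),
                   adj$chrom2, format(adj$pos2 - 1, scientific = FALSE, trim = TRUE),
                   format(adj$pos2, scientific = FALSE, trim = TRUE),
                   name, 0L, adj$orient1, adj$orient2, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read adjacencies from the minimal TSV dialect
#'
#' Columns: `chrom1, pos1, orient1, chrom2, pos2, orient2[, set_id]`, with
#' positions already 1-based.  A header line is tolerated.
#'
#' @param path File path.
#' @return An [adjacencies()] table.
#' @export
read_adjacency_tsv <- function(path) {
  ln <- .read_lines_table(path)
  if (length(ln) && grepl("^chrom", ln[1L], ignore.case = TRUE)) ln <- ln[-1L]
  if (!length(ln))
    return(adjacencies(character(0), numeric(0), character(0),
                       character(0), numeric(0), character(0), set_id = character(0)))
  fields <- strsplit(ln, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("malformed TSV line ", which(nf < 6L)[1L], ": expected >= 6 columns",
         call. = FALSE)
  get <- function(i) vapply(fields, `[[`, character(1), i)
  set_id <- if (all(nf >= 7L)) get(7L) else "set1"
  adjacencies(get(1L), as.numeric(get(2L)), get(3L),
              get(4L), as.numeric(get(5L)), get(6L), set_id = set_id)
}

#' Read a copy-number segmentation
#'
#' Accepts SEG-style TSV with columns `(sample,) chrom, start, end, value`
#' (5 or 4 columns; a header line is tolerated) or plain BED4
#' (`chrom, start, end, value`).  Four-column input is interpreted as BED
#' (0-based half-open start, converted to 1-based inclusive); five-column
#' input as SEG (1-based inclusive).  Segments are validated as sorted and
#' non-overlapping per chromosome.
#'
#' @param path File path.
#' @return A [copy_segments()] table.
#' @export
read_seg <- function(path) {
  ln <- .read_lines_table(path)
  if (!length(ln))
    return(copy_segments(character(0), numeric(0), numeric(0), numeric(0)))
  fields <- strsplit(ln, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop("malformed segmentation line ", which(nf < 4L)[1L],
         ": expected 4 (BED) or 5 (SEG) columns", call. = FALSE)
  five <- nf[1L] >= 5L
  ## header detection: start column non-numeric
  start_col <- if (five) 3L else 2L
  if (is.na(suppressWarnings(as.numeric(fields[[1L]][start_col])))) {
    fields <- fields[-1L]
    if (!length(fields))
      return(copy_segments(character(0), numeric(0), numeric(0), numeric(0)))
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  if (five) {
    chrom <- get(2L); start <- as.numeric(get(3L))
    end <- as.numeric(get(4L)); value <- as.numeric(get(5L))
  } else {
    chrom <- get(1L); start <- as.numeric(get(2L)) + 1
    end <- as.numeric(get(3L)); value <- as.numeric(get(4L))
  }
  if (anyNA(start) || anyNA(end) || anyNA(value))
    stop("malformed segmentation line ",
         which(is.na(start) | is.na(end) | is.na(value))[1L],
         ": non-numeric fields", call. = FALSE)
  copy_segments(chrom, start, end, value)
}

#' Write a copy-number segmentation as SEG
#'
#' Five tab-separated columns (`sample, chrom, start, end, value`, 1-based
#' inclusive) with a header line.
#'
#' @param segments A [copy_segments()] table.
#' @param path Output file path.
#' @param sample Sample identifier for the first column.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path, sample = "sample1") {
  df <- data.frame(sample = sample, chrom = segments$chrom,
                   start = format(segments$start, scientific = FALSE, trim = TRUE),
                   end = format(segments$end, scientific = FALSE, trim = TRUE),
                   value = segments$value, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("sample", "chrom", "start", "end", "value"))
  invisible(path)
}
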