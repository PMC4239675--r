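# End-to-end analysis: filter -> match counterparts -> assign Delta ->
# classify -> per-set measures.

#' Open-adjacency analysis of one or more adjacency sets
#'
#' Runs the full detection pipeline on a table of somatic novel adjacencies
#' and (optionally) a copy-number segmentation: drops adjacency sets smaller
#' than `min_set_size`, matches breakends into counterpart pairs at distance
#' `D`, maps segmentation boundaries to breakends as a signed step function
#' with breakpoint intervals of length `L`, classifies every adjacency as
#' open or closed via counterpart-asymmetry and copy-number asymmetry, and
#' summarises each set with the open adjacency rate (OAR) and the
#' copy-number asymmetry enrichment (CAE).
#'
#' Without a segmentation, classification uses counterpart evidence only and
#' CAE is reported as `NA`.
#'
#' @param adjacencies An [adjacencies()] table, or the path of a BEDPE file
#'   ([read_bedpe()]).
#' @param segments A [copy_segments()] table, the path of a SEG/BED4 file
#'   ([read_seg()]), or `NULL`.
#' @param D Counterpart-matching distance threshold in bp (default 2000).
#' @param L Breakpoint-interval length in bp (default 10000).
#' @param min_set_size Minimum adjacency-set size retained (default 15).
#' @param scope `"set"` (default): counterpart evidence is restricted to the
#'   analyzed adjacency set; `"genome"`: breakends of all sets are pooled
#'   for matching and counterpart evidence.
#' @param k_hat Optional named numeric vector mapping set ids to externally
#'   estimated (k>2)-break fractions in `[0, 1]`.
#' @return An object of class `"openadj"`: a list with `measures` (one row
#'   per retained set), `calls` (per-adjacency classification), `pairing`
#'   (counterpart pairs; a list per set when `scope = "set"`), `delta`
#'   (change-in-copy profile, or `NULL`), `adjacencies`, `dropped_sets`, and
#'   `params`.  Methods: `print`, `summary`, `plot`, `as.data.frame`.
#' @examples
#' bedpe <- system.file("extdata", "toy.bedpe", package = "openadj")
#' seg <- system.file("extdata", "toy.seg", package = "openadj")
#' fit <- openadj(bedpe, seg, min_set_size = 1)
#' fit
#' summary(fit)
#' @export
openadj <- function(adjacencies, segments = NULL, D = 2000, L = 10000,
                    min_set_size = 15, scope = c("set", "genome"),
                    k_hat = NULL) {
  scope <- match.arg(scope)
  stopifnot(D >= 0, L > 0, min_set_size >= 1)
  if (is.character(adjacencies)) adjacencies <- read_bedpe(adjacencies)
  if (is.character(segments)) segments <- read_seg(segments)
  if (!inherits(adjacencies, "oa_adjacencies")) adjacencies <- as_adjacencies(adjacencies)
  if (!is.null(k_hat) && length(k_hat) && any(k_hat < 0 | k_hat > 1, na.rm = TRUE))
    stop("k_hat values must lie in [0, 1]", call. = FALSE)

  all_sets <- unique(adjacencies$set_id)
  adj <- filter_small_sets(adjacencies, min_set_size)
  dropped <- setdiff(all_sets, unique(adj$set_id))
  if (!nrow(adj))
    stop("no adjacency set with at least ", min_set_size, " adjacencies", call. = FALSE)

  intervals <- if (!is.null(segments)) boundary_intervals(segments, L) else NULL
  sets <- unique(adj$set_id)

  genome_pairing <- if (scope == "genome") match_counterparts(adj, D) else NULL
  pairing <- list()
  calls_rows <- list()
  delta_rows <- list()
  measures_rows <- list()
  for (s in sets) {
    a <- adj[adj$set_id == s, , drop = FALSE]
    class(a) <- class(adj)
    pr <- if (scope == "genome") genome_pairing else match_counterparts(a, D)
    pairing[[s]] <- pr
    if (!is.null(intervals)) {
      dl <- assign_delta(a, intervals)
      p_delta <- attr(dl, "p_delta")
      delta_rows[[s]] <- dl
    } else {
      dl <- NULL
      p_delta <- NA_real_
    }
    ## counterpart evidence (partners of counterparts) follows the scope
    evidence <- if (scope == "genome") adj else a
    cl <- classify_adjacencies_scoped(a, pr, dl, evidence)
    calls_rows[[s]] <- cl
    kh <- if (!is.null(k_hat) && s %in% names(k_hat)) unname(k_hat[[s]]) else NA_real_
    measures_rows[[s]] <- set_measures(cl, p_delta, kh)
  }
  calls <- do.call(rbind, calls_rows)
  rownames(calls) <- NULL
  class(calls) <- c("oa_calls", "data.frame")
  measures <- do.call(rbind, measures_rows)
  rownames(measures) <- NULL
  delta <- if (length(delta_rows)) {
    d <- do.call(rbind, delta_rows)
    rownames(d) <- NULL
    class(d) <- c("oa_delta", "data.frame")
    d
  } else NULL

  structure(list(
    measures = measures, calls = calls,
    pairing = if (scope == "genome") genome_pairing else pairing,
    delta = delta, adjacencies = adj, dropped_sets = dropped,
    params = list(D = D, L = L, min_set_size = min_set_size, scope = scope,
                  has_segments = !is.null(segments))),
    class = "openadj")
}

## classify with counterpart evidence possibly wider than the set itself:
## `evidence` supplies the adjacency partners of matched counterparts
classify_adjacencies_scoped <- function(a, pairing, delta, evidence) {
  if (identical(evidence, a)) return(classify_adjacencies(a, pairing, delta))
  cp_of <- .pairing_lookup(pairing)
  partner_of <- .partner_lookup(evidence)
  n <- nrow(a)
  cp_asym <- logical(n)
  for (i in seq_len(n)) {
    cp_asym[i] <- .asym_from(a$uid1[i], a$uid2[i], cp_of, partner_of) ||
      .asym_from(a$uid2[i], a$uid1[i], cp_of, partner_of)
  }
  if (is.null(delta)) {
    cn_asym <- rep(FALSE, n)
  } else {
    d <- stats::setNames(delta$delta, delta$uid)
    cn_asym <- unname(d[a$uid1] != d[a$uid2])
  }
  out <- data.frame(set_id = a$set_id, adj_id = a$adj_id,
                    counterpart_asym = cp_asym, copy_asym = cn_asym,
                    open = cp_asym | cn_asym, stringsAsFactors = FALSE)
  class(out) <- c("oa_calls", "data.frame")
  out
}

#' @export
print.openadj <- function(x, ...) {
  m <- x$measures
  cat("Open-adjacency analysis\n")
  cat(sprintf("  %d adjacency set(s), %d adjacencies (D = %s bp, L = %s bp, scope = %s)\n",
              nrow(m), sum(m$n_adjacencies),
              format(x$params$D, scientific = FALSE),
              format(x$params$L, scientific = FALSE), x$params$scope))
  if (length(x$dropped_sets))
    cat(sprintf("  dropped %d set(s) below %d adjacencies\n",
                length(x$dropped_sets), x$params$min_set_size))
  cat(sprintf("  open adjacencies: %d (%d counterpart-asymmetric, %d copy-asymmetric)\n",
              sum(m$n_open), sum(x$calls$counterpart_asym), sum(m$n_copy_asym)))
  cat(sprintf("  OAR: mean %.3f, range [%.3f, %.3f]\n",
              mean(m$oar), min(m$oar), max(m$oar)))
  if (any(!is.na(m$cae)))
    cat(sprintf("  CAE: mean %.3f over %d set(s) with defined value\n",
                mean(m$cae, na.rm = TRUE), sum(!is.na(m$cae))))
  else if (x$params$has_segments)
    cat("  CAE: undefined for every set (p_delta is 0 or 1)\n")
  else
    cat("  CAE: not computed (no segmentation supplied)\n")
  invisible(x)
}

#' @export
summary.openadj <- function(object, ...) {
  structure(list(measures = object$measures, params = object$params,
                 dropped_sets = object$dropped_sets),
            class = "summary.openadj")
}

#' @export
print.summary.openadj <- function(x, ...) {
  cat("Per-set measures:\n")
  m <- x$measures
  num <- vapply(m, is.numeric, logical(1))
  m[num] <- lapply(m[num], function(v) round(v, 4))
  print.data.frame(m, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.openadj <- function(x, ...) x$measures

#' Plot per-set measures
#'
#' With `k_hat` annotations present, draws the statistic against `k_hat`
#' (one point per adjacency set, sized by set size); otherwise a histogram
#' of the statistic across sets.
#'
#' @param x An [openadj()] fit.
#' @param statistic `"oar"` or `"cae"`.
#' @param ... Passed to the underlying plotting function.
#' @return `x`, invisibly.
#' @export
plot.openadj <- function(x, statistic = c("oar", "cae"), ...) {
  statistic <- match.arg(statistic)
  m <- x$measures
  v <- m[[statistic]]
  if (any(!is.na(m$k_hat))) {
    ok <- !is.na(m$k_hat) & !is.na(v)
    graphics::plot(m$k_hat[ok], v[ok],
                   xlab = "external (k>2)-break fraction k_hat",
                   ylab = toupper(statistic),
                   cex = 0.5 + 1.5 * sqrt(m$n_adjacencies[ok] / max(m$n_adjacencies[ok])),
                   pch = 19, ...)
  } else {
    graphics::hist(v[!is.na(v)], xlab = toupper(statistic),
                   main = paste(toupper(statistic), "across adjacency sets"), ...)
  }
  invisible(x)
}
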