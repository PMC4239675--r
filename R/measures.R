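# Set-level measures: open adjacency rate (OAR), copy-number asymmetry
# enrichment (CAE), and cohort-level comparisons.
#
#   OAR(A, N) = |O| / |A|
#   CAE(A)    = |C| / (2 * p_delta * (1 - p_delta) * |A|)
#
# where O is the set of adjacencies flagged open by either signature, C the
# subset with copy-number asymmetry, and p_delta the fraction of breakends
# of the set with nonzero Delta.  Under the Bernoulli model in which Delta
# values are -1/0, equal across 2-break adjacencies and independent across
# (k>2)-break adjacencies with P(Delta != 0) = p_delta, E|C| =
# 2 p (1-p) |A^k| and CAE estimates the (k>2)-break fraction |A^k|/|A|.

#' Open adjacency rate
#'
#' Fraction of an adjacency set flagged open; a lower bound on the fraction
#' of adjacencies formed in (k>2)-breaks.
#'
#' @param calls A [classify_adjacencies()] result (non-empty).
#' @return Numeric in `[0, 1]`.
#' @export
oar <- function(calls) {
  if (!nrow(calls)) stop("OAR is undefined for an empty adjacency set", call. = FALSE)
  mean(calls$open)
}

#' Copy-number asymmetry enrichment
#'
#' Estimates the (k>2)-break adjacency fraction from copy-number asymmetry
#' alone, independent of breakend positions.
#'
#' @param calls A [classify_adjacencies()] result (non-empty); only the
#'   `copy_asym` column is used.
#' @param p_delta Fraction of breakends of the same set with nonzero Delta,
#'   e.g. `attr(assign_delta(...), "p_delta")`.
#' @return Non-negative numeric, or `NA` with a warning when `p_delta` is 0
#'   or 1 (the enrichment denominator vanishes).
#' @export
cae <- function(calls, p_delta) {
  if (!nrow(calls)) stop("CAE is undefined for an empty adjacency set", call. = FALSE)
  stopifnot(is.numeric(p_delta), length(p_delta) == 1L)
  if (is.na(p_delta) || p_delta <= 0 || p_delta >= 1) {
    warning("CAE undefined: p_delta = ", format(p_delta),
            " (no information in copy-number asymmetry)", call. = FALSE)
    return(NA_real_)
  }
  sum(calls$copy_asym) / (2 * p_delta * (1 - p_delta) * nrow(calls))
}

#' Summarise one adjacency set
#'
#' @param calls A [classify_adjacencies()] result for one set.
#' @param p_delta The set's breakend-level nonzero-Delta fraction
#'   (`NA` when no segmentation was supplied).
#' @param k_hat Optional externally estimated (k>2)-break fraction.
#' @return A one-row data.frame: `set_id`, `n_adjacencies`, `n_open`,
#'   `n_copy_asym`, `p_delta`, `oar`, `cae`, `k_hat`.
#' @export
set_measures <- function(calls, p_delta = NA_real_, k_hat = NA_real_) {
  stopifnot(nrow(calls) > 0L, length(unique(calls$set_id)) == 1L)
  if (!is.na(k_hat) && (k_hat < 0 || k_hat > 1))
    stop("k_hat must lie in [0, 1]", call. = FALSE)
  cae_val <- if (is.na(p_delta) || p_delta <= 0 || p_delta >= 1) NA_real_
             else suppressWarnings(cae(calls, p_delta))
  data.frame(set_id = calls$set_id[1L], n_adjacencies = nrow(calls),
             n_open = sum(calls$open), n_copy_asym = sum(calls$copy_asym),
             p_delta = p_delta, oar = oar(calls), cae = cae_val, k_hat = k_hat,
             stringsAsFactors = FALSE)
}

#' Compare a statistic between two groups of adjacency sets
#'
#' Wilcoxon rank-sum (Mann-Whitney) test on a per-set statistic between two
#' labeled groups, e.g. sets classified as stepwise versus one-off.  Small
#' untied samples use the exact null distribution; otherwise the normal
#' approximation with tie correction is used (via [stats::wilcox.test()]).
#'
#' @param measures_a,measures_b Data.frames of per-set measures (rows of
#'   [set_measures()]), both non-empty.
#' @param statistic `"oar"` or `"cae"`.
#' @param alternative `"two.sided"` (default), `"greater"` (group a tends
#'   larger) or `"less"`.
#' @return A list of class `htest` with the rank-sum statistic `W` and
#'   `p.value`.
#' @export
group_compare <- function(measures_a, measures_b, statistic = c("oar", "cae"),
                          alternative = c("two.sided", "greater", "less")) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  a <- measures_a[[statistic]]
  b <- measures_b[[statistic]]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    stop("both groups must contain at least one set with a defined ", statistic,
         call. = FALSE)
  if (length(a) + length(b) <= 16L)
    .exact_ranksum(a, b, alternative)
  else
    suppressWarnings(stats::wilcox.test(a, b, alternative = alternative))
}

## Exact rank-sum test by enumeration of all group assignments, valid with
## ties (average ranks).  stats::wilcox.test falls back to the normal
## approximation whenever ties are present, so small cohorts are enumerated
## here instead.
.exact_ranksum <- function(a, b, alternative) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  obs <- sum(r[seq_len(na)])
  mu <- na * (na + nb + 1) / 2
  sums <- utils::combn(r, na, sum)
  eps <- 1e-8
  p <- switch(alternative,
    two.sided = mean(abs(sums - mu) >= abs(obs - mu) - eps),
    greater = mean(sums >= obs - eps),
    less = mean(sums <= obs + eps))
  w <- obs - na * (na + 1) / 2
  structure(list(statistic = c(W = w), p.value = p,
                 alternative = alternative,
                 method = "Exact Wilcoxon rank sum test (full enumeration)",
                 data.name = "group a vs group b"),
            class = "htest")
}

#' Correlate a statistic with the external (k>2)-break annotation
#'
#' Pearson correlation between a per-set statistic and the externally
#' supplied estimate `k_hat` of the (k>2)-break adjacency fraction.
#'
#' @param measures Data.frame of per-set measures with a `k_hat` column; at
#'   least 3 sets must have both values present and each side must vary.
#' @param statistic `"oar"` or `"cae"`.
#' @return A list with `r`, `p.value`, `n`, and the underlying `htest`.
#' @export
correlate_khat <- function(measures, statistic = c("oar", "cae")) {
  statistic <- match.arg(statistic)
  ok <- !is.na(measures$k_hat) & !is.na(measures[[statistic]])
  x <- measures[[statistic]][ok]
  y <- measures$k_hat[ok]
  if (length(x) < 3L)
    stop("need at least 3 sets with both ", statistic, " and k_hat", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation with k_hat is undefined", call. = FALSE)
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p.value = ht$p.value, n = length(x), test = ht)
}

#' Drop adjacency sets below a minimum size
#'
#' @param adj An [adjacencies()] table (possibly several sets).
#' @param min_size Minimum number of adjacencies a set must contain
#'   (default 15).
#' @return The table restricted to sets with at least `min_size` rows.
#' @export
filter_small_sets <- function(adj, min_size = 15) {
  stopifnot(min_size >= 1)
  if (!nrow(adj)) return(adj)
  sizes <- table(adj$set_id)
  keep <- names(sizes)[sizes >= min_size]
  out <- adj[adj$set_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
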