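# Classification of adjacencies as open or closed.
#
# An adjacency {x, y} created by a 2-break is "closed": the counterparts
# x' and y' were necessarily fused to each other.  Adjacencies created by
# (k>2)-breaks are "open".  Two observable signatures identify open
# adjacencies: counterpart-asymmetry (a counterpart of one endpoint is fused
# to something other than the other endpoint's counterpart) and copy-number
# asymmetry (Delta(x) != Delta(y)); copy-asymmetric adjacencies are provably
# open under the no-breakpoint-reuse and all-ends-fused assumptions.

## lookup helpers shared by the classification functions
.pairing_lookup <- function(pairing) {
  stats::setNames(c(pairing$uid_minus, pairing$uid_plus),
                  c(pairing$uid_plus, pairing$uid_minus))
}

.partner_lookup <- function(adj) {
  stats::setNames(c(adj$uid2, adj$uid1), c(adj$uid1, adj$uid2))
}

## counterpart-asymmetry evidence from endpoint `a` against endpoint `b`:
## a's matched counterpart cp belongs to an adjacency {cp, w}; the evidence
## holds unless w is exactly b's matched counterpart.  An unmatched b cannot
## contradict the evidence (had w been b's true counterpart, the matcher
## would have paired them).
.asym_from <- function(a, b, cp_of, partner_of) {
  cp <- cp_of[a]
  if (is.na(cp)) return(FALSE)
  w <- partner_of[cp]
  if (is.na(w) || w == a) return(FALSE)   # counterpart inside A itself: no evidence
  bcp <- cp_of[b]
  is.na(bcp) || bcp != w
}

#' Counterpart-asymmetry of one adjacency
#'
#' `TRUE` iff some endpoint of `A = {x, y}` has a matched counterpart whose
#' own adjacency partner is not the other endpoint's counterpart (including
#' the case where the other endpoint has no matched counterpart).  `FALSE`
#' when neither endpoint has a matched counterpart.
#'
#' @param A A one-row [adjacencies()] table (or a row index into `adj`).
#' @param pairing A [match_counterparts()] result.
#' @param adj The full adjacency table supplying partners of counterparts.
#' @return Logical scalar.
#' @export
counterpart_asymmetric <- function(A, pairing, adj) {
  if (is.numeric(A)) A <- adj[A, , drop = FALSE]
  stopifnot(nrow(A) == 1L)
  cp_of <- .pairing_lookup(pairing)
  partner_of <- .partner_lookup(adj)
  .asym_from(A$uid1, A$uid2, cp_of, partner_of) ||
    .asym_from(A$uid2, A$uid1, cp_of, partner_of)
}

#' Copy-number asymmetry of one adjacency
#'
#' `TRUE` iff the change-in-copy values at the two endpoints differ,
#' `Delta(x) != Delta(y)`.
#'
#' @param A A one-row [adjacencies()] table.
#' @param delta An [assign_delta()] profile covering both endpoints.
#' @return Logical scalar.
#' @export
copy_asymmetric <- function(A, delta) {
  stopifnot(nrow(A) == 1L)
  d <- stats::setNames(delta$delta, delta$uid)
  d1 <- d[A$uid1]; d2 <- d[A$uid2]
  if (is.na(d1) || is.na(d2))
    stop("delta profile is missing adjacency endpoints: ",
         paste(c(A$uid1, A$uid2)[c(is.na(d1), is.na(d2))], collapse = ", "),
         call. = FALSE)
  unname(d1 != d2)
}

#' Classify every adjacency of a set as open or closed
#'
#' An adjacency is called open when it shows counterpart-asymmetry or
#' copy-number asymmetry; both component flags are reported so that CAE can
#' be computed from copy-number asymmetry alone.
#'
#' @param adj An [adjacencies()] table.
#' @param pairing A [match_counterparts()] result for (at least) the
#'   endpoints of `adj`.
#' @param delta An [assign_delta()] profile covering all endpoints of `adj`;
#'   `NULL` disables copy-number evidence (all `copy_asym = FALSE`).
#' @return A data.frame of class `"oa_calls"`: `set_id`, `adj_id`,
#'   `counterpart_asym`, `copy_asym`, `open`.
#' @export
classify_adjacencies <- function(adj, pairing, delta = NULL) {
  cp_of <- .pairing_lookup(pairing)
  partner_of <- .partner_lookup(adj)
  n <- nrow(adj)
  cp_asym <- logical(n)
  for (i in seq_len(n)) {
    cp_asym[i] <- .asym_from(adj$uid1[i], adj$uid2[i], cp_of, partner_of) ||
      .asym_from(adj$uid2[i], adj$uid1[i], cp_of, partner_of)
  }
  if (is.null(delta)) {
    cn_asym <- rep(FALSE, n)
  } else {
    d <- stats::setNames(delta$delta, delta$uid)
    d1 <- d[adj$uid1]; d2 <- d[adj$uid2]
    if (anyNA(d1) || anyNA(d2))
      stop("delta profile does not cover all adjacency endpoints", call. = FALSE)
    cn_asym <- unname(d1 != d2)
  }
  out <- data.frame(set_id = adj$set_id, adj_id = adj$adj_id,
                    counterpart_asym = cp_asym, copy_asym = cn_asym,
                    open = cp_asym | cn_asym, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("oa_calls", "data.frame")
  out
}
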