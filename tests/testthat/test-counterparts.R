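# Helper: build an adjacency set whose first endpoints are the breakends of
# interest, each fused to a far-away "+" partner on chr9 that can never match.
adj_with_partners <- function(chrom, pos, orient) {
  n <- length(pos)
  adjacencies(chrom, pos, orient,
              rep("chr9", n), 1e6 * seq_len(n), rep("+", n))
}

test_that("counterpart matching applies the four criteria", {
  ## two convergent breakends from different adjacencies, nothing nearby
  a <- adj_with_partners("chr1", c(100, 101), c("+", "-"))
  pr <- match_counterparts(a, D = 2000)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$pos_plus, 100)
  expect_equal(pr$pos_minus, 101)
  expect_equal(pr$distance, 1)

  ## criterion 3: the same two breakends forming a detected adjacency
  b <- adjacencies("chr1", 100, "+", "chr1", 101, "-")
  expect_equal(nrow(match_counterparts(b, D = 2000)), 0L)

  ## criterion 4: an intervening breakend blocks the wide pair
  c3 <- adj_with_partners("chr1", c(100, 150, 160), c("+", "+", "-"))
  pr3 <- match_counterparts(c3, D = 2000)
  expect_equal(nrow(pr3), 1L)
  expect_equal(pr3$pos_plus, 150)
  expect_equal(pr3$pos_minus, 160)

  ## criterion 1: distance beyond D
  d <- adj_with_partners("chr1", c(100, 3000), c("+", "-"))
  expect_equal(nrow(match_counterparts(d, D = 2000)), 0L)
  ## but matched once D is large enough
  expect_equal(nrow(match_counterparts(d, D = 2900)), 1L)

  ## criterion 2: divergent and parallel orientations never match
  e <- adj_with_partners("chr1", c(100, 101), c("-", "+"))
  expect_equal(nrow(match_counterparts(e, D = 2000)), 0L)

  ## coincident convergent breakends (distance 0) are accepted
  f <- adj_with_partners("chr1", c(500, 500), c("+", "-"))
  expect_equal(match_counterparts(f, D = 2000)$distance, 0)
})

test_that("matching agrees with the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:60) {
    inst <- random_instance(n_breakends = sample(6:60, 1),
                            n_chrom = sample(1:3, 1), span = 5000)
    D <- sample(c(0, 10, 100, 1000), 1)
    got <- match_counterparts(inst, D)
    want <- brute_match(inst, D)
    expect_equal(got$uid_plus, want$uid_plus)
    expect_equal(got$uid_minus, want$uid_minus)
  }
})

test_that("no breakend is ever matched twice and the pairing is monotone in D", {
  set.seed(202)
  for (i in 1:30) {
    inst <- random_instance(n_breakends = 40, n_chrom = 2, span = 3000)
    p1 <- match_counterparts(inst, 50)
    p2 <- match_counterparts(inst, 500)
    expect_false(anyDuplicated(c(p1$uid_plus, p1$uid_minus)) > 0)
    expect_false(anyDuplicated(c(p2$uid_plus, p2$uid_minus)) > 0)
    k1 <- paste(p1$uid_plus, p1$uid_minus)
    k2 <- paste(p2$uid_plus, p2$uid_minus)
    expect_true(all(k1 %in% k2))
  }
})

test_that("orientation spectrum counts isolated qualifying pairs", {
  a <- adj_with_partners("chr1", c(10, 20), c("+", "-"))
  ## restrict to chr1 to keep the far-away partners out of the window
  s <- orientation_spectrum(oa_breakends(a)[1:2, ], D = 100)
  expect_equal(unname(s$counts[["+-"]]), 1)
  expect_equal(s$total, 1)
  expect_equal(sum(s$proportions), 1)

  ## no same-chromosome pair within D
  b <- adj_with_partners("chr1", c(10, 5000), c("+", "-"))
  s0 <- orientation_spectrum(oa_breakends(b)[1:2, ], D = 100)
  expect_equal(s0$total, 0)
})

test_that("convergence enrichment is a one-sided binomial test against 1/4", {
  sp <- structure(list(D = 2000,
                       counts = c("+-" = 25, "-+" = 25, "++" = 25, "--" = 25),
                       total = 100,
                       proportions = c("+-" = .25, "-+" = .25, "++" = .25, "--" = .25)),
                  class = "oa_spectrum")
  res <- convergence_enrichment(sp)
  expect_equal(res$proportion, 0.25)
  ## independent oracle: exact binomial tail sum P(X >= 25), X ~ Bin(100, 1/4)
  expect_equal(res$p.value, sum(dbinom(25:100, 100, 0.25)), tolerance = 1e-12)

  sp2 <- structure(list(D = 2000,
                        counts = c("+-" = 100, "-+" = 0, "++" = 0, "--" = 0),
                        total = 100,
                        proportions = c("+-" = 1, "-+" = 0, "++" = 0, "--" = 0)),
                   class = "oa_spectrum")
  res2 <- convergence_enrichment(sp2)
  expect_equal(res2$proportion, 1)
  expect_equal(res2$p.value, 0.25^100, tolerance = 1e-12)

  sp0 <- structure(list(D = 10, counts = c("+-" = 0, "-+" = 0, "++" = 0, "--" = 0),
                        total = 0, proportions = rep(NA_real_, 4)),
                   class = "oa_spectrum")
  expect_error(convergence_enrichment(sp0), "empty")
})

test_that("the D sweep reports one spectrum row per threshold", {
  set.seed(9)
  inst <- random_instance(n_breakends = 80, n_chrom = 2, span = 20000)
  sw <- sweep_orientation_spectrum(inst, D = c(10, 100, 1000))
  expect_equal(nrow(sw), 3L)
  expect_true(all(abs(rowSums(sw[, c("p_conv", "p_div", "p_pp", "p_mm")]) - 1) < 1e-12 |
                  sw$total == 0))
  ## totals can only grow with D
  expect_true(all(diff(sw$total) >= 0))
})
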