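test_that("boundary intervals are centered, signed, and length L", {
  seg <- copy_segments(c("chr1", "chr1"), c(1, 1001), c(1000, 2000), c(2, 1))
  iv <- boundary_intervals(seg, L = 10)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$center, 1000.5)
  expect_equal(iv$sign, -1)
  expect_equal(iv$hi - iv$lo + 1, 10)

  ## equal adjacent values produce no interval
  seg2 <- copy_segments(c("chr1", "chr1"), c(1, 1001), c(1000, 2000), c(2, 2))
  expect_equal(nrow(boundary_intervals(seg2, L = 10)), 0L)

  ## three segments with values (2, 3, 1): signs (+1, -1)
  seg3 <- copy_segments(rep("chr1", 3), c(1, 1001, 2001), c(1000, 2000, 3000),
                        c(2, 3, 1))
  iv3 <- boundary_intervals(seg3, L = 10)
  expect_equal(iv3$sign, c(1, -1))

  ## a gap wider than max_gap yields no boundary
  seg4 <- copy_segments(c("chr1", "chr1"), c(1, 60001), c(1000, 70000), c(2, 1))
  expect_equal(nrow(boundary_intervals(seg4, L = 10000)), 0L)

  ## overlap is rejected at construction
  expect_error(boundary_intervals(
    data.frame(chrom = "chr1", start = c(1, 500), end = c(1000, 2000),
               value = c(2, 1))), "overlapping")
})

test_that("delta step function follows orientation across a matched boundary", {
  ## copy rises 2 -> 3 at position 50000/50001
  seg <- copy_segments(c("chr1", "chr1"), c(1, 50001), c(50000, 100000), c(2, 3))
  iv <- boundary_intervals(seg, L = 10000)

  ## unique "+" breakend inside the rising interval: Delta = +1
  a <- adjacencies("chr1", 48000, "+", "chr9", 500000, "+")
  d <- assign_delta(a, iv)
  expect_equal(d$delta[d$chrom == "chr1"], 1)

  ## the same boundary read by a "-" breakend: Delta = -1 (counterpart side
  ## minus retained side)
  b <- adjacencies("chr1", 52000, "-", "chr9", 500000, "+")
  db <- assign_delta(b, iv)
  expect_equal(db$delta[db$chrom == "chr1"], -1)

  ## breakend far from every boundary: Delta = 0
  cc <- adjacencies("chr1", 90000, "+", "chr9", 500000, "+")
  expect_equal(assign_delta(cc, iv)$delta, c(0, 0))

  ## two breakends inside one interval: uniqueness violated, both 0
  e <- adjacencies("chr1", 48000, "+", "chr1", 52000, "-")
  de <- assign_delta(e, iv)
  expect_equal(de$delta, c(0, 0))
  expect_equal(attr(de, "p_delta"), 0)

  ## p_delta is the fraction of breakends with nonzero Delta
  expect_equal(attr(d, "p_delta"), 0.5)
})

test_that("a breakend inside two overlapping intervals is ambiguous", {
  seg <- copy_segments(rep("chr1", 3), c(1, 50001, 56001), c(50000, 56000, 100000),
                       c(2, 3, 2))
  iv <- boundary_intervals(seg, L = 10000)
  expect_equal(nrow(iv), 2L)
  ## 53000 lies in both intervals
  a <- adjacencies("chr1", 53000, "+", "chr9", 500000, "+")
  expect_equal(assign_delta(a, iv)$delta, c(0, 0))
})

test_that("delta is invariant to uniform shifts of the copy scale", {
  set.seed(33)
  for (i in 1:10) {
    inst <- random_instance(n_breakends = 30, n_chrom = 2, span = 50000)
    seg <- random_segmentation(n_chrom = 2, span = 50000)
    shifted <- copy_segments(seg$chrom, seg$start, seg$end, seg$value + 7)
    d1 <- assign_delta(inst, boundary_intervals(seg, L = 2000))
    d2 <- assign_delta(inst, boundary_intervals(shifted, L = 2000))
    expect_equal(d1$delta, d2$delta)
  }
})

test_that("delta assignment agrees with the brute-force membership scan", {
  set.seed(44)
  for (i in 1:40) {
    inst <- random_instance(n_breakends = sample(6:60, 1), n_chrom = 2, span = 50000)
    seg <- random_segmentation(n_chrom = 2, span = 50000,
                               n_seg = sample(3:8, 1))
    iv <- boundary_intervals(seg, L = sample(c(500, 2000, 10000), 1))
    got <- assign_delta(inst, iv)
    want <- brute_delta(inst, iv)
    expect_equal(got$delta[match(want$uid, got$uid)], want$delta)
  }
})

test_that("an exact simulated 2-break deletion yields Delta = -1 at both ends", {
  found <- FALSE
  for (s in 1:60) {
    h <- simulate_history(c(chr1 = 1e6), events = 2, circle_loss_p = 1, seed = s)
    ob <- observe(h)
    if (nrow(ob$adjacencies) == 1L && nrow(ob$segments) == 3L) {
      found <- TRUE
      iv <- boundary_intervals(ob$segments, L = 10000)
      d <- assign_delta(ob$adjacencies, iv)
      expect_equal(d$delta, c(-1, -1))
      ## deletion adjacency is copy-symmetric, hence not called open
      calls <- classify_adjacencies(ob$adjacencies,
                                    match_counterparts(ob$adjacencies, 2000), d)
      expect_false(calls$copy_asym)
      expect_false(calls$open)
      break
    }
  }
  expect_true(found)
})
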