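test_that("histories are deterministic given a seed and validate inputs", {
  h1 <- simulate_history(c(chrA = 1e6, chrB = 1e6), c(2, 3, 2), seed = 42)
  h2 <- simulate_history(c(chrA = 1e6, chrB = 1e6), c(2, 3, 2), seed = 42)
  expect_identical(h1$truth, h2$truth)
  o1 <- observe(h1, seed = 7)
  o2 <- observe(h2, seed = 7)
  expect_identical(o1$adjacencies, o2$adjacencies)
  expect_identical(o1$segments, o2$segments)

  ## byte-identical serialization across re-runs
  f1 <- tempfile(); f2 <- tempfile()
  write_bedpe(o1$adjacencies, f1)
  write_bedpe(o2$adjacencies, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(simulate_history(c(chrA = 1e6), c(2, 1)), "k >= 2")
  expect_error(simulate_history(c(chrA = 50), c(2, 2, 2)), "too small")
})

test_that("every event creates k adjacencies and cut sites never repeat", {
  set.seed(1)
  for (s in 1:10) {
    ks <- sample(2:6, 3, replace = TRUE)
    h <- simulate_history(c(chrA = 2e6, chrB = 2e6), ks, seed = 1000 + s)
    expect_equal(nrow(h$truth), sum(ks))
    expect_equal(as.vector(table(h$truth$event)[as.character(seq_along(ks))]), ks)
    ## no breakpoint reuse, and the minimum spacing holds per chromosome
    for (ch in unique(h$cuts$chrom)) {
      p <- sort(h$cuts$pos[h$cuts$chrom == ch])
      if (length(p) > 1L) expect_true(min(diff(p)) >= h$params$min_spacing)
    }
  }
})

test_that("retained material is conserved: coverage equals segment counting", {
  for (s in 1:5) {
    h <- simulate_history(c(chrA = 5e5, chrB = 5e5), c(2, 3, 4),
                          circle_loss_p = 0, seed = 2000 + s)
    ob <- observe(h, baseline_copy = 0)
    ## nothing lost: every reference base still covered exactly once
    expect_equal(unique(ob$segments$value), 1)
    expect_equal(sum(ob$segments$end - ob$segments$start + 1), 1e6)
  }
  ## with circle loss, total coverage is reference minus lost circle footprint
  for (s in 1:5) {
    h <- simulate_history(c(chrA = 5e5, chrB = 5e5), c(2, 3, 4),
                          circle_loss_p = 1, seed = 3000 + s)
    ob <- observe(h, baseline_copy = 0)
    lost <- sum(vapply(h$threads, function(t) {
      if (t$lost) sum(t$segs$end - t$segs$start + 1) else 0
    }, numeric(1)))
    covered <- sum((ob$segments$end - ob$segments$start + 1) * ob$segments$value)
    expect_equal(covered + lost, 1e6)
    expect_true(all(ob$segments$value %in% c(0, 1)))
  }
})

test_that("a 3-break with nothing lost yields 3 open adjacencies", {
  h <- simulate_history(c(chrA = 1e6), 3, circle_loss_p = 0, seed = 5)
  ob <- observe(h)
  expect_equal(nrow(ob$adjacencies), 3L)
  expect_equal(ob$truth_fraction, 1)
  calls <- classify_adjacencies(ob$adjacencies,
                                match_counterparts(ob$adjacencies, 2000),
                                assign_delta(ob$adjacencies,
                                             boundary_intervals(ob$segments)))
  expect_true(all(calls$open))
})

test_that("observation noise behaves as configured", {
  h <- simulate_history(c(chrA = 3e6, chrB = 3e6), rep(2, 10), seed = 8)
  full <- observe(h)
  n_full <- nrow(full$adjacencies)
  expect_gt(n_full, 5)

  ## dropout thins the observed set binomially
  set.seed(99)
  kept <- replicate(40, nrow(observe(h, dropout_p = 0.5)$adjacencies))
  expect_lt(abs(mean(kept) - 0.5 * n_full), 3 * sqrt(n_full * 0.25))

  ## jitter moves positions but never flips orientations or loses rows
  jit <- observe(h, jitter_sd = 50, seed = 123)
  expect_equal(nrow(jit$adjacencies), n_full)
  expect_setequal(unique(c(jit$adjacencies$orient1, jit$adjacencies$orient2)),
                  unique(c(full$adjacencies$orient1, full$adjacencies$orient2)))
  shift <- abs(sort(c(jit$adjacencies$pos1, jit$adjacencies$pos2)) -
               sort(c(full$adjacencies$pos1, full$adjacencies$pos2)))
  expect_true(all(shift <= 150))  # clipped at 3 standard deviations
  expect_false(identical(jit$adjacencies$pos1, full$adjacencies$pos1) &&
               identical(jit$adjacencies$pos2, full$adjacencies$pos2))
})

test_that("truth fraction reflects the event mix", {
  h2 <- simulate_history(c(chrA = 2e6), c(2, 2, 2), seed = 21)
  expect_equal(observe(h2)$truth_fraction, 0)
  hk <- simulate_history(c(chrA = 2e6), 20, seed = 22)
  expect_equal(observe(hk)$truth_fraction, 1)
})

test_that("the Bernoulli cohort realizes the stated endpoint model", {
  ## frac_k = 0: endpoint values are shared, never asymmetric
  c0 <- bernoulli_cohort(500, 0, 0.4, seed = 1)
  expect_equal(sum(c0$delta_x != c0$delta_y), 0L)
  expect_true(all(c0$delta_x %in% c(-1, 0)))

  ## frac_k = 1, p = 0.5: asymmetric share concentrates near 2p(1-p) = 0.5
  set.seed(2)
  share <- mean(replicate(30, {
    ch <- bernoulli_cohort(400, 1, 0.5)
    mean(ch$delta_x != ch$delta_y)
  }))
  expect_lt(abs(share - 0.5), 0.02)

  expect_equal(attr(bernoulli_cohort(100, 0.6, 0.4, seed = 3), "truth_fraction"), 0.6)
})
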