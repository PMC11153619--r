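mk_track <- function(contig, start, end, value)
  data.table::data.table(contig = contig, start = start, end = end,
                         value = value)

test_that("track union refines breakpoints and treats absence as zero", {
  a <- mk_track("chr1", 0, 10, 5)
  b <- mk_track("chr1", 5, 15, 7)
  u <- union_tracks(a, b)
  expect_equal(u$start, c(0, 5, 10))
  expect_equal(u$end, c(5, 10, 15))
  expect_equal(u$value_a, c(5, 5, 0))
  expect_equal(u$value_b, c(0, 7, 7))

  same <- union_tracks(a, a)
  expect_equal(same$value_a, same$value_b)

  empty_b <- union_tracks(a, a[0])
  expect_equal(empty_b$value_a, 5)
  expect_equal(empty_b$value_b, 0)
})

test_that("union preserves each input's mass and matches per-base enumeration", {
  mass <- function(tr, col = "value") sum(tr[[col]] * (tr$end - tr$start))
  set.seed(51)
  for (i in 1:20) {
    mk_rand <- function() {
      bp <- sort(sample(0:200, sample(2:10, 1)))
      n <- length(bp) - 1
      keep <- runif(n) < 0.7
      mk_track("c", bp[-length(bp)][keep], bp[-1][keep],
               sample(0:30, sum(keep), replace = TRUE))
    }
    a <- mk_rand(); b <- mk_rand()
    u <- union_tracks(a, b)
    expect_equal(mass(u, "value_a"), mass(a))
    expect_equal(mass(u, "value_b"), mass(b))
    u_a <- u[, .(contig, start, end, value = value_a)]
    u_b <- u[, .(contig, start, end, value = value_b)]
    for (base in sample(0:199, 25)) {
      expect_equal(oracle_value_at(u_a, base), oracle_value_at(a, base))
      expect_equal(oracle_value_at(u_b, base), oracle_value_at(b, base))
    }
  }
})

test_that("the modal peak is the span-dominant nonzero value", {
  expect_equal(modal_normalize(mk_track("c", 0, 1e6, 40))$modal, 40)
  two <- mk_track("c", c(0, 6e6), c(6e6, 1e7), c(30, 15))
  nm <- modal_normalize(two)
  expect_equal(nm$modal, 30)
  expect_equal(nm$track$value, c(1.0, 0.5))
  ## zero spans are excluded from the histogram
  withzero <- mk_track("c", c(0, 9e6), c(9e6, 1e7), c(0, 20))
  expect_equal(modal_normalize(withzero)$modal, 20)
  expect_error(modal_normalize(mk_track("c", 0, 100, 0)), "all-zero")
  ## ties break toward the smaller value
  tie <- mk_track("c", c(0, 100), c(100, 200), c(25, 50))
  expect_equal(modal_normalize(tie)$modal, 25)
})

test_that("modal estimation matches the span-weighted histogram oracle and is scale invariant", {
  set.seed(52)
  for (i in 1:50) {
    bp <- sort(sample(0:5000, sample(3:40, 1)))
    tr <- mk_track("c", bp[-length(bp)], bp[-1],
                   sample(0:50, length(bp) - 1, replace = TRUE))
    if (all(tr$value == 0)) next
    nm <- modal_normalize(tr)
    expect_equal(nm$modal, oracle_modal(tr))
    k <- sample(2:7, 1)
    scaled <- data.table::copy(tr)[, value := value * k]
    nm_k <- modal_normalize(scaled)
    expect_equal(nm_k$modal, k * nm$modal)
    expect_equal(nm_k$track$value, nm$track$value)
  }
})

test_that("base selection uses inclusive male bounds and a strict female bound", {
  thr <- coverage_thresholds()
  joint <- data.table::data.table(
    contig = "c", start = 0:4, end = 1:5,
    female = c(0.00, 0.00, 0.049, 0.05, 0.00),
    male = c(0.50, 1.00, 0.25, 0.50, 0.75))
  sel <- select_sex_specific_bases(joint, thr)
  ## bases 0 (0.5/0), 2 (0.25/0.049), 4 (0.75/0) selected; 1 is diploid in
  ## the male pool, 3 hits the strict female bound
  expect_equal(sel$start, c(0, 2, 4))
  expect_equal(sel$end, c(1, 3, 5))
})

test_that("selection is pointwise: re-chunking intervals changes nothing", {
  joint <- data.table::data.table(
    contig = "c", start = c(0, 100), end = c(100, 300),
    female = c(0.01, 0.01), male = c(0.5, 0.5))
  rechunked <- data.table::data.table(
    contig = "c", start = c(0, 40, 100, 200), end = c(40, 100, 200, 300),
    female = 0.01, male = 0.5)
  expect_equal(select_sex_specific_bases(joint),
               select_sex_specific_bases(rechunked))
})

test_that("selected runs merge by gap and count only selected bases", {
  runs <- data.table::data.table(contig = "c", start = c(99, 299),
                                 end = c(199, 399))  # 1-based [100..199],[300..399]
  cl <- cluster_selected_bases(runs, max_gap = 9000)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_bases, 200)
  expect_equal(cl$span, 300)
  expect_equal(cl$start, 100)
  expect_equal(cl$end, 399)

  one <- cluster_selected_bases(
    data.table::data.table(contig = "c", start = 10, end = 11), 9000)
  expect_equal(one$n_bases, 1)

  ## gap wider than max_gap separates clusters; n_bases is conserved
  far <- data.table::data.table(contig = "c", start = c(0, 20000),
                                end = c(100, 20050))
  cl2 <- cluster_selected_bases(far, max_gap = 9000)
  expect_equal(nrow(cl2), 2L)
  expect_equal(sum(cl2$n_bases), 150)
})

test_that("cluster base counts always sum to the total selected bases", {
  set.seed(53)
  for (i in 1:20) {
    bp <- sort(sample.int(1e5, 2 * sample(1:30, 1)))
    runs <- data.table::data.table(contig = "c",
                                   start = bp[c(TRUE, FALSE)],
                                   end = bp[c(FALSE, TRUE)])
    runs <- runs[start < end]
    gap <- sample(c(0, 100, 9000), 1)
    cl <- cluster_selected_bases(runs, gap)
    expect_equal(sum(cl$n_bases), sum(runs$end - runs$start))
  }
})

test_that("the full coverage scan recovers the planted Y insertion and is asymmetric in the sexes", {
  sim <- quick_sim(seed = 54L)
  cov <- run_coverage_scan(sim$female_coverage, sim$male_coverage)
  expect_equal(cov$modal_female, 40)
  expect_equal(cov$modal_male, 40)
  top <- cov$clusters[1]
  tr <- sim$truth$y_insertion
  expect_true(intervals_overlap(top$contig, top$start, top$end,
                                tr$contig, tr$start, tr$end))
  expect_gte(top$n_bases, 0.9 * (tr$end - tr$start + 1))

  ## swapping the pools leaves (at most) background-level selection
  swapped <- run_coverage_scan(sim$male_coverage, sim$female_coverage)
  expect_lt(swapped$n_selected_bases, 0.01 * cov$n_selected_bases + 1000)
})
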