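test_that("pool genotypes classify by the depth and allele-fraction windows", {
  cfg <- screen_config()
  expect_equal(classify_pool_genotype(c(20, 18, 1, 1), cfg), "HOM_REF")   # f = 0.05
  expect_equal(classify_pool_genotype(c(10, 10, 9, 11), cfg), "HET")      # f = 0.50
  expect_equal(classify_pool_genotype(c(4, 4, 3, 3), cfg), "LOW_DEPTH")   # total 14
  expect_equal(classify_pool_genotype(c(0, 0, 20, 20), cfg), "HOM_ALT")   # f = 1.00
  expect_equal(classify_pool_genotype(c(30, 30, 15, 25), cfg), "AMBIGUOUS") # f = 0.40
  expect_equal(classify_pool_genotype(c(0, 0, 0, 0), cfg), "LOW_DEPTH")
})

test_that("window bounds are inclusive at the printed thresholds", {
  cfg <- screen_config()
  expect_equal(classify_fraction(7 / 100, 100, cfg), "HOM_REF")
  expect_equal(classify_fraction(93 / 100, 100, cfg), "HOM_ALT")
  expect_equal(classify_fraction(45 / 100, 100, cfg), "HET")
  expect_equal(classify_fraction(55 / 100, 100, cfg), "HET")
  expect_equal(classify_fraction(8 / 100, 100, cfg), "AMBIGUOUS")
  expect_equal(classify_fraction(9 / 20, 20, cfg), "HET")   # 0.45 as a ratio
})

test_that("XY mode keeps male-HET / female-homozygous variants and drops the rest", {
  v <- random_variants(4, seed = 1)[1:2]
  ## male HET + female HOM_REF -> retained
  v[1, c("female_ref_fwd", "female_ref_rev", "female_alt_fwd",
         "female_alt_rev") := .(30L, 28L, 1L, 1L)]
  v[1, c("male_ref_fwd", "male_ref_rev", "male_alt_fwd",
         "male_alt_rev") := .(15L, 14L, 15L, 16L)]
  ## female HET -> dropped in XY mode
  v[2, c("female_ref_fwd", "female_ref_rev", "female_alt_fwd",
         "female_alt_rev") := .(10L, 10L, 10L, 10L)]
  v[2, c("male_ref_fwd", "male_ref_rev", "male_alt_fwd",
         "male_alt_rev") := .(20L, 20L, 0L, 0L)]
  out <- screen_variants(v, screen_config(mode = "XY"))
  expect_equal(out$candidates$pos, v$pos[1])
  expect_equal(out$candidates$male_class, "HET")
  expect_equal(sum(out$drop_counts), 1L)
  expect_equal(out$n_input, 2L)
})

test_that("screening matches the independent per-rule oracle on random variants", {
  v <- random_variants(500, seed = 11)
  for (mode in c("XY", "ZW")) {
    got <- screen_variants(v, screen_config(mode = mode))$candidates$pos
    expect_equal(got, v$pos[oracle_screen_keep(v, mode)])
  }
})

test_that("swapping pool labels interchanges the XY and ZW screens", {
  v <- random_variants(400, seed = 12)
  xy_swapped <- screen_variants(swap_pools(v), screen_config(mode = "XY"))
  zw <- screen_variants(v, screen_config(mode = "ZW"))
  expect_equal(xy_swapped$candidates$pos, zw$candidates$pos)
  expect_equal(xy_swapped$drop_counts, zw$drop_counts)
})

test_that("raising min_depth or narrowing the het window never adds candidates", {
  v <- random_variants(600, seed = 13)
  n_at <- function(md, lo = 0.45, hi = 0.55)
    nrow(screen_variants(v, screen_config(min_depth = md, het_low = lo,
                                          het_high = hi))$candidates)
  counts <- vapply(c(1, 5, 15, 25, 40), n_at, numeric(1))
  expect_true(all(diff(counts) <= 0))
  widths <- vapply(c(0.01, 0.03, 0.05, 0.10), function(w)
    n_at(15, 0.5 - w, 0.5 + w), numeric(1))
  expect_true(all(diff(widths) >= 0))
})

test_that("the retained set does not depend on input order", {
  v <- random_variants(300, seed = 14)
  shuffled <- v[sample(.N)]
  a <- screen_variants(v, screen_config())$candidates
  b <- screen_variants(shuffled, screen_config())$candidates
  expect_equal(sort(a$pos), sort(b$pos))
})

test_that("planted-site retention matches the closed-form binomial model and background false positives stay below 1e-2", {
  ## P(retain | planted XY site, both depths >= min) under the sim model:
  ## depth ~ Poisson(lambda) conditioned >= 15, male alt ~ Binom(d, 0.5),
  ## female alt ~ Binom(d, eps)
  lambda <- 40; eps <- 0.002
  d <- 15:120
  wd <- dpois(d, lambda) / sum(dpois(d, lambda))
  p_het <- sum(wd * vapply(d, function(dd) {
    k <- 0:dd
    sum(dbinom(k[k / dd >= 0.45 - 1e-9 & k / dd <= 0.55 + 1e-9], dd, 0.5))
  }, numeric(1)))
  p_hom <- sum(wd * vapply(d, function(dd) {
    k <- 0:dd
    sum(dbinom(k[k / dd <= 0.07 + 1e-9 | k / dd >= 0.93 - 1e-9], dd, eps))
  }, numeric(1)))
  p_expect <- p_het * p_hom

  n_pass <- 0; n_ret <- 0; n_bg <- 0; n_fp <- 0
  for (seed in 101:103) {
    sim <- quick_sim(seed)
    cfg <- screen_config()
    ann <- poolsex:::annotate_genotypes(sim$variants, cfg)
    planted <- ann[sim$truth$divergent_sites, on = c("contig", "pos"),
                   nomatch = NULL]
    pass <- planted[female_depth >= 15 & male_depth >= 15]
    ret <- screen_variants(sim$variants, cfg)$candidates
    n_pass <- n_pass + nrow(pass)
    n_ret <- n_ret + sum(pass$pos %in% ret$pos)
    bg <- ann[!sim$truth$divergent_sites, on = c("contig", "pos")]
    n_bg <- n_bg + nrow(bg)
    n_fp <- n_fp + sum(bg$pos %in% ret$pos)
  }
  obs <- n_ret / n_pass
  se <- sqrt(p_expect * (1 - p_expect) / n_pass)
  expect_lt(abs(obs - p_expect), 3 * se + 0.01)
  expect_lt(n_fp / n_bg, 1e-2)
})
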