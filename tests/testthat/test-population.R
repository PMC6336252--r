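test_that("founders are homozygous, divergent, and give an all-het F1", {
  map <- build_map(3L, 7L, 5)
  f <- make_founders(map)
  expect_true(all(dosages(f$parent1) == 2L))
  expect_true(all(dosages(f$parent2) == 0L))
  expect_equal(sum(heterozygosity(f$parent1)), 0)
  f1 <- make_f1(map)
  expect_true(all(dosages(f1) == 1L))
  # a gamete from a fully homozygous individual equals its haplotype
  set.seed(1)
  g <- make_gamete(f$parent1, map)
  expect_identical(g, f$parent1$h1[1L, ])
})

test_that("F1 gametes recombine at the Haldane fraction for 1 cM", {
  map <- build_map(1L, 2L, 1)
  f <- make_founders(map)
  set.seed(42)
  f2 <- make_f2(f$parent1, f$parent2, 20000L, map)
  pool <- haplotype_matrix(f2)   # 40,000 F1 gametes
  rec <- mean(pool[, 1L] != pool[, 2L])
  c_expect <- recombination_fraction(1)
  expect_equal(rec, c_expect, tolerance = 3 * sqrt(c_expect / nrow(pool)) / c_expect)
  # both parental types near (1-c)/2 each
  expect_equal(mean(pool[, 1L] == 1 & pool[, 2L] == 1), (1 - c_expect) / 2,
               tolerance = 0.02)
})

test_that("markers on different groups assort independently", {
  map <- build_map(2L, 1L, 1)
  f <- make_founders(map)
  set.seed(7)
  f2 <- make_f2(f$parent1, f$parent2, 8000L, map)
  pool <- haplotype_matrix(f2)
  D <- mean(pool[, 1L] * pool[, 2L]) - mean(pool[, 1L]) * mean(pool[, 2L])
  expect_equal(D, 0, tolerance = 0.01)
})

test_that("the F2 base has Mendelian genotype frequencies and linkage LD", {
  map <- build_map(1L, 2L, 1)
  f <- make_founders(map)
  set.seed(5)
  f2 <- make_f2(f$parent1, f$parent2, 5000L, map)
  d <- dosages(f2)
  tab <- table(factor(d[, 1L], 0:2)) / nrow(d)
  expect_equal(as.numeric(tab), c(0.25, 0.5, 0.25), tolerance = 0.05)
  expect_equal(unname(allele_freqs(f2)), c(0.5, 0.5), tolerance = 0.03)
  expect_equal(mean(heterozygosity(f2)), 0.5, tolerance = 0.03)
  # adjacent-marker gametic D = (1 - 2c)/4 ~ 0.2451 at 1 cM
  pool <- haplotype_matrix(f2)
  D <- mean(pool[, 1L] * pool[, 2L]) - mean(pool[, 1L]) * mean(pool[, 2L])
  expect_equal(D, (1 - 2 * recombination_fraction(1)) / 4, tolerance = 0.01)
  expect_error(make_f2(f$parent1, f$parent2, 1L, map), "at least 2")
  expect_error(make_f2(f$parent1, f$parent1, 10L, map), "divergent")
})

test_that("heterozygosity halves each selfing generation", {
  map <- build_map(10L, 11L, 10)
  set.seed(33)
  series <- simulate_series(map, 500L, "selfing", generations = 3L)
  h <- vapply(series, function(p) mean(heterozygosity(p)), numeric(1L))
  expect_equal(unname(h), c(0.5, 0.25, 0.125, 0.0625), tolerance = 0.05)
  expect_equal(names(series), c("F2", "S1", "S2", "S3"))
})

test_that("advancement preserves population size, markers and labels", {
  map <- build_map(2L, 6L, 5)
  set.seed(2)
  f <- make_founders(map)
  f2 <- make_f2(f$parent1, f$parent2, 40L, map)
  for (sys in c("selfing", "random_mating", "backcross")) {
    off <- advance(f2, sys, map)
    expect_equal(pop_size(off), 40L)
    expect_equal(ncol(off$h1), map$n_markers)
    expect_equal(off$gen_index, 1L)
    expect_equal(off$generation,
                 switch(sys, selfing = "S1", random_mating = "A1",
                        backcross = "Bc1"))
  }
  expect_error(advance(f2, "mutation", map), "arg")
})

test_that("gametic D decays by (1 - c) per random-mating generation", {
  map <- build_map(1L, 2L, 20)  # c ~ 0.1648
  cfrac <- recombination_fraction(20)
  set.seed(9)
  f <- make_founders(map)
  f2 <- make_f2(f$parent1, f$parent2, 20000L, map)
  Dof <- function(p) {
    pool <- haplotype_matrix(p)
    mean(pool[, 1L] * pool[, 2L]) - mean(pool[, 1L]) * mean(pool[, 2L])
  }
  a1 <- advance(f2, "random_mating", map, mode = "meiosis")
  expect_equal(Dof(a1) / Dof(f2), 1 - cfrac, tolerance = 0.05)
})

test_that("allele resampling collapses LD to the 1/(2N) baseline", {
  map <- build_map(1L, 40L, 1)
  set.seed(12)
  f <- make_founders(map)
  f2 <- make_f2(f$parent1, f$parent2, 500L, map)
  a1 <- advance(f2, "random_mating", map, mode = "allele_resampling")
  tab <- ld_decay_table(list(A1 = a1), map)
  overall <- attr(tab, "overall_mean_r2")[["A1"]]
  baseline <- 1 / (2 * 500)
  expect_gt(overall, baseline / 3)
  expect_lt(overall, baseline * 3)
})

test_that("backcrossing to the F1 keeps expected heterozygosity at 1/2", {
  map <- build_map(2L, 11L, 10)
  set.seed(21)
  series <- simulate_series(map, 400L, "backcross", generations = 2L)
  expect_equal(mean(heterozygosity(series$Bc1)), 0.5, tolerance = 0.03)
  expect_equal(mean(heterozygosity(series$Bc2)), 0.5, tolerance = 0.03)
  # single-locus check: offspring inherit the F1 gamete allele with prob 1/2
  expect_equal(mean(allele_freqs(series$Bc2)), 0.5, tolerance = 0.03)
})

test_that("simulation streams are bit-reproducible under a fixed seed", {
  map <- build_map(2L, 6L, 5)
  run <- function() {
    set.seed(99)
    simulate_series(map, 30L, "random_mating", generations = 2L,
                    mode = "meiosis")
  }
  expect_identical(run(), run())
})
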