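test_that("binomial weights match the expansion of (1/2 + 1/2)^s", {
  w <- binomial_weights(19)
  expect_length(w, 20L)
  expect_equal(sum(w), 1)
  expect_equal(w[10L], 92378 / 524288)          # choose(19, 9) / 2^19
  expect_equal(w, rev(w))                       # symmetric
  expect_equal(binomial_weights(1), c(0.5, 0.5))
  expect_equal(binomial_weights(0), 1)
  expect_error(binomial_weights(-1), "non-negative")
})

test_that("QTL placement puts two QTL per group at the default quartiles", {
  map <- build_map()
  q <- assign_qtl(map)
  expect_length(q, 20L)
  expect_equal(tabulate(map$group[q]), rep(2L, 10L))
  expect_equal(unique(map$pos_cM[q]), c(25, 75))
  one_group <- build_map(1L, 101L, 1)
  expect_equal(map_pos <- build_map(1L, 101L, 1)$pos_cM[assign_qtl(one_group)],
               c(25, 75))
  expect_error(assign_qtl(build_map(3L, 1L, 1)), "cannot place")
})

test_that("genetic values follow the weighted additive-dominance score", {
  map <- build_map()
  for (da in c(0, 0.5, 1)) {
    arch <- trait_architecture(map, dominance_ratio = da, mu = 0.3)
    q <- length(arch$qtl_indices)
    all2 <- matrix(2L, 1L, q)
    allhet <- matrix(1L, 1L, q)
    all0 <- matrix(0L, 1L, q)
    expect_equal(genetic_value(all2, arch), 0.3 + 1)
    expect_equal(genetic_value(allhet, arch), 0.3 + da)
    expect_equal(genetic_value(all0, arch), 0.3 - 1)
  }
  arch <- trait_architecture(map, 1)
  expect_error(genetic_value(matrix(3L, 1L, 20L), arch), "0, 1 or 2")
  # with d/a = 0 the value depends on the dosage score only
  arch0 <- trait_architecture(map, 0)
  set.seed(3)
  dos <- matrix(sample(0:2, 40L, replace = TRUE), 2L, 20L)
  expect_equal(genetic_value(dos, arch0),
               drop((dos - 1) %*% arch0$add_effects))
})

test_that("maximum genetic value is attained at the favourable homozygote", {
  map <- build_map(2L, 11L, 10)
  arch <- trait_architecture(map, dominance_ratio = 1,
                             qtl_indices = assign_qtl(map, c(20, 80)))
  set.seed(8)
  dos <- matrix(sample(0:2, 500L * 4L, replace = TRUE), 500L, 4L)
  expect_lte(max(genetic_value(dos, arch)), 1 + 1e-12)
  expect_equal(genetic_value(matrix(2L, 1L, 4L), arch), 1)
})

test_that("closed-form F2 genetic variance matches theory and simulation", {
  map <- build_map(1L, 101L, 1)
  arch1 <- trait_architecture(map, 0, qtl_indices = 51L)  # single locus, a = 1
  expect_equal(genetic_variance_f2(arch1, method = "closed_form"), 0.5)
  arch <- trait_architecture(build_map(), 0)
  expect_equal(genetic_variance_f2(arch, method = "closed_form"),
               sum(arch$weights^2) / 2)
  # empirical variance matches the closed form when QTL are unlinked
  map10 <- build_map(10L, 3L, 40)
  archu <- trait_architecture(map10, 0, qtl_indices = which(map10$pos_cM == 40))
  set.seed(14)
  f <- make_founders(map10)
  f2 <- make_f2(f$parent1, f$parent2, 6000L, map10)
  emp <- genetic_variance_f2(archu, f2)
  expect_equal(emp, genetic_variance_f2(archu, method = "closed_form"),
               tolerance = 0.08)
  expect_error(genetic_variance_f2(archu, NULL, "empirical"), "population")
})

test_that("environmental variance follows the heritability identity", {
  expect_equal(environmental_variance(1, 0.5), 1)
  expect_equal(environmental_variance(3, 0.3), 7)
  expect_equal(environmental_variance(1, 0.7), 3 / 7)
  expect_error(environmental_variance(1, 1), "between 0 and 1")
  expect_error(environmental_variance(1, 0), "between 0 and 1")
  expect_error(environmental_variance(-1, 0.5), "positive")
})

test_that("phenotypes decompose exactly and hit the target heritability", {
  map <- build_map()
  arch <- trait_architecture(map, 0)
  set.seed(19)
  f <- make_founders(map)
  f2 <- make_f2(f$parent1, f$parent2, 500L, map)
  ph <- simulate_phenotypes(f2, arch, h2 = 0.3)
  expect_equal(ph$P, ph$G + ph$E)
  realized <- stats::var(ph$G) / stats::var(ph$P)
  expect_equal(realized, 0.3, tolerance = 0.06 / 0.3)
  # noise-free hook
  ph0 <- simulate_phenotypes(f2, arch, sigma2_e = 0)
  expect_equal(ph0$P, ph0$G)
  # determinism
  set.seed(77); a <- simulate_phenotypes(f2, arch, h2 = 0.5)
  set.seed(77); b <- simulate_phenotypes(f2, arch, h2 = 0.5)
  expect_identical(a, b)
})
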