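test_that("marker coding matches the centered parameterization", {
  coding <- code_markers(matrix(c(2L, 1L, 0L), 3L, 1L), 0.5)
  expect_equal(drop(coding$W), c(1, 0, -1))
  expect_equal(drop(coding$S), c(-0.5, 0.5, -0.5))
  # fixed marker: all-zero columns
  fixed <- code_markers(matrix(2L, 4L, 1L), 1)
  expect_true(all(fixed$W == 0) && all(fixed$S == 0))
  expect_false(fixed$polymorphic)
  # at the observed frequency every W column is exactly centered;
  # S columns center under Hardy-Weinberg genotype proportions
  set.seed(4)
  p_true <- runif(10L, 0.2, 0.8)
  dos <- sapply(p_true, function(pp) rbinom(2000L, 2L, pp))
  p <- colMeans(dos) / 2
  cd <- code_markers(dos, p)
  expect_equal(colSums(cd$W), rep(0, 10L), tolerance = 1e-9)
  expect_equal(colMeans(cd$S), rep(0, 10L), tolerance = 0.03)
  expect_error(code_markers(matrix(3L, 1L, 1L), 0.5), "0, 1 or 2")
})

test_that("relationship matrices have the expected scale and structure", {
  # single marker, p = 0.5, individuals AA / Aa / aa
  coding <- code_markers(matrix(c(2L, 1L, 0L), 3L, 1L), 0.5)
  grm <- build_grm(coding)
  expect_equal(diag(grm$Ga), c(2, 0, 2))
  expect_equal(grm$Ga, tcrossprod(matrix(c(1, 0, -1))) / 0.5)
  expect_true(isSymmetric(grm$Gd))
  # identical genotype rows give identical relationship rows
  dos <- rbind(c(2L, 0L, 1L), c(2L, 0L, 1L), c(0L, 1L, 2L))
  grm2 <- build_grm(code_markers(dos, colMeans(dos) / 2))
  expect_equal(grm2$Ga[1L, ], grm2$Ga[2L, ])
  # large unselected F2: mean diagonal near 1
  sc <- small_f2_scenario(n = 400L, seed = 23L)
  g <- build_grm(code_markers(dosages(sc$f2), allele_freqs(sc$f2)))
  expect_equal(mean(diag(g$Ga)), 1, tolerance = 0.1)
  expect_equal(mean(diag(g$Gd)), 1, tolerance = 0.15)
  expect_error(build_grm(code_markers(matrix(2L, 3L, 2L), c(1, 1))),
               "monomorphic")
})

test_that("REML finds the optimum of the directly computed likelihood", {
  sc <- small_f2_scenario(n = 60L, seed = 31L, map = build_map(2L, 6L, 10))
  grm <- build_grm(code_markers(dosages(sc$f2), allele_freqs(sc$f2)))
  fit <- reml_fit(sc$y, grm$Ga, grm$Gd)
  oracle <- reml_oracle(sc$y, grm$Ga, grm$Gd)
  # the fitted likelihood may not fall below the oracle's optimum
  expect_gte(fit$loglik, oracle$loglik - 1e-4)
  expect_equal(reml_loglik_direct(c(fit$sigma2_a, fit$sigma2_d, fit$sigma2_e),
                                  sc$y, grm$Ga, grm$Gd),
               fit$loglik, tolerance = 1e-6)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("REML recovers generating variance components", {
  sc <- small_f2_scenario(n = 400L, seed = 37L)
  grm <- build_grm(code_markers(dosages(sc$f2), allele_freqs(sc$f2)))
  n <- 400L
  La <- chol(grm$Ga + diag(1e-6, n))
  Ld <- chol(grm$Gd + diag(1e-6, n))
  s2 <- c(a = 3, d = 0, e = 7)
  set.seed(41)
  h2_hat <- replicate(4L, {
    y <- drop(crossprod(La, rnorm(n))) * sqrt(s2["a"]) + rnorm(n, 0, sqrt(s2["e"]))
    f <- reml_fit(y, grm$Ga, grm$Gd)
    f$sigma2_a / (f$sigma2_a + f$sigma2_d + f$sigma2_e)
  })
  expect_equal(mean(h2_hat), 0.3, tolerance = 0.33)
  # pure noise: genetic components collapse to the floor
  set.seed(43)
  fnull <- reml_fit(rnorm(n), grm$Ga, grm$Gd)
  expect_lt(fnull$sigma2_a + fnull$sigma2_d,
            0.05 * (fnull$sigma2_a + fnull$sigma2_d + fnull$sigma2_e))
})

test_that("marker effects equal the closed-form ridge solution", {
  fx <- make_fixture("toy_training")
  dos <- fx$dosages; y <- fx$y
  p <- colMeans(dos) / 2
  coding <- code_markers(dos, p)
  grm <- build_grm(coding)
  fit <- list(sigma2_a = 0.4, sigma2_d = 0.1, sigma2_e = 1)
  mme <- solve_effects(y, coding, grm, fit, method = "mme")
  # oracle: direct inversion of the ridge normal equations
  Tm <- cbind(1, coding$W, coding$S)
  lam <- c(0, rep(fit$sigma2_e / (fit$sigma2_a / grm$sum2pq), 3L),
           rep(fit$sigma2_e / (fit$sigma2_d / grm$sum2pq_sq), 3L))
  beta <- solve(crossprod(Tm) + diag(lam), crossprod(Tm, y))
  expect_equal(mme$ma, beta[2:4], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(mme$md, beta[5:7], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(mme$intercept, beta[1L], tolerance = 1e-10, ignore_attr = TRUE)
  # infinite-shrinkage limit: effects vanish
  tiny <- solve_effects(y, coding, grm,
                        list(sigma2_a = 1e-12, sigma2_d = 1e-12, sigma2_e = 1),
                        method = "mme")
  expect_lt(max(abs(c(tiny$ma, tiny$md))), 1e-10)
})

test_that("marker-level and relationship-level routes give the same model", {
  sc <- small_f2_scenario(n = 150L, seed = 47L)
  dos <- dosages(sc$f2)
  coding <- code_markers(dos, allele_freqs(sc$f2))
  grm <- build_grm(coding)
  fit <- reml_fit(sc$y, grm$Ga, grm$Gd)
  back <- solve_effects(sc$y, coding, grm, fit, method = "backsolve")
  mme <- solve_effects(sc$y, coding, grm, fit, method = "mme")
  expect_equal(back$ma, mme$ma, tolerance = 1e-6)
  expect_equal(back$md, mme$md, tolerance = 1e-6)
  # G-BLUP route: u = (sigma2_a Ga + sigma2_d Gd) P y equals W ma + S md
  u_grm <- drop((fit$sigma2_a * grm$Ga + fit$sigma2_d * grm$Gd) %*% fit$Py)
  u_mark <- drop(coding$W %*% back$ma + coding$S %*% back$md)
  expect_equal(u_mark, u_grm, tolerance = 1e-6)
})

test_that("prediction contracts hold", {
  sc <- small_f2_scenario(n = 120L, seed = 53L)
  mod <- gblup_train(sc$f2, sc$y)
  # validation = training reproduces the training GEBVs
  expect_equal(predict(mod, sc$f2), attr(mod, "gebv"), tolerance = 1e-10)
  expect_error(predict(mod, matrix(1L, 3L, 5L)), "mismatch")
  # single-marker toy model: AA - aa difference is 2 ma
  coding <- code_markers(matrix(c(2L, 1L, 0L, 1L), 4L, 1L), 0.5)
  grm <- build_grm(coding)
  toy <- solve_effects(c(1.2, 0.4, -0.9, 0.1), coding, grm,
                       list(sigma2_a = 1, sigma2_d = 0.5, sigma2_e = 1),
                       method = "mme")
  pr <- predict(toy, matrix(c(2L, 0L), 2L, 1L))
  expect_equal(pr[1L] - pr[2L], 2 * toy$ma[1L])
})

test_that("reliability is a squared correlation with guarded edge cases", {
  set.seed(59)
  x <- rnorm(500)
  expect_equal(reliability(x, x), 1)
  expect_equal(reliability(-x, x), 1)
  expect_lt(reliability(rnorm(500), x), 0.05)
  expect_error(reliability(rep(1, 5), rnorm(5)), "constant")
  expect_error(reliability(x, x[-1]), "equal length")
})

test_that("in-sample reliability increases with heritability", {
  gains <- vapply(c(61L, 62L), function(seed) {
    sc_lo <- small_f2_scenario(n = 200L, seed = seed, h2 = 0.3)
    set.seed(seed + 1000L)
    y_hi <- sc_lo$G + rnorm(200L, 0, sqrt(environmental_variance(
      stats::var(sc_lo$G), 0.7)))
    r_lo <- reliability(attr(gblup_train(sc_lo$f2, sc_lo$y), "gebv"), sc_lo$G)
    r_hi <- reliability(attr(gblup_train(sc_lo$f2, y_hi), "gebv"), sc_lo$G)
    r_hi - r_lo
  }, numeric(1L))
  expect_gt(mean(gains), 0)
})
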