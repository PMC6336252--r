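# Independent oracles and small shared builders used across test files.

# Restricted log-likelihood of y = 1b + ua + ud + e, computed directly
# from its definition with dense solves (independent of reml_fit()).
reml_loglik_direct <- function(theta, y, Ga, Gd) {
  n <- length(y)
  X <- matrix(1, n, 1L)
  V <- theta[1L] * Ga + theta[2L] * Gd + theta[3L] * diag(n)
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  ll <- -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                  drop(crossprod(y, P %*% y)))
  as.numeric(ll)
}

# Derivative-free maximisation of the direct restricted likelihood on the
# log-variance scale, restarted from several points.
reml_oracle <- function(y, Ga, Gd, starts = NULL) {
  if (is.null(starts)) {
    vp <- stats::var(y)
    starts <- list(log(rep(vp / 3, 3)),
                   log(c(vp / 2, vp / 10, vp / 2)),
                   log(c(vp / 10, vp / 2, vp / 2)))
  }
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, function(lt) -reml_loglik_direct(exp(lt), y, Ga, Gd),
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(theta = exp(best$par), loglik = -best$value)
}

# A small F2 scenario shared by several gblup tests.
small_f2_scenario <- function(n = 200L, seed = 11L, dominance = 0.5,
                              h2 = 0.5, map = build_map(2L, 21L, 5)) {
  set.seed(seed)
  founders <- make_founders(map)
  f2 <- make_f2(founders$parent1, founders$parent2, n, map)
  arch <- trait_architecture(map, dominance_ratio = dominance,
                             qtl_indices = assign_qtl(map, c(25, 75)))
  G <- genetic_value(f2, arch)
  ph <- simulate_phenotypes(f2, arch, h2 = h2)
  list(map = map, f2 = f2, arch = arch, G = G, y = ph$P)
}
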