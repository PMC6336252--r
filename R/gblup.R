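#' Centered additive and dominance marker codings
#'
#' Builds the incidence matrices of the additive-dominance marker model
#' from a dosage matrix and per-marker allele frequencies. For a marker
#' with allele frequency `p` (and `q = 1 - p`):
#' \describe{
#'   \item{W (additive)}{dosage 2 -> `2 - 2p`; dosage 1 -> `1 - 2p`;
#'     dosage 0 -> `-2p`.}
#'   \item{S (dominance)}{dosage 2 -> `-2q^2`; dosage 1 -> `2pq`;
#'     dosage 0 -> `-2p^2`.}
#' }
#' Both columns have mean zero when `p` is the observed frequency of the
#' coded individuals. Markers monomorphic at `p` in {0, 1} yield all-zero
#' columns and are excluded from downstream variance denominators.
#'
#' @param dosages Integer matrix (individuals x markers), values 0/1/2.
#' @param freqs Per-marker allele frequencies used for centering. In the
#'   multigeneration pipeline these are always the training-set
#'   frequencies, including when coding validation individuals.
#' @return List with matrices `W` and `S`, the `freqs` used, and the
#'   logical vector `polymorphic`.
#' @export
code_markers <- function(dosages, freqs) {
  dosages <- as.matrix(dosages)
  if (any(dosages != 0L & dosages != 1L & dosages != 2L))
    stop("dosages must be 0, 1 or 2")
  if (length(freqs) != ncol(dosages))
    stop("'freqs' must have one entry per marker")
  if (any(freqs < 0 | freqs > 1)) stop("allele frequencies must lie in [0, 1]")
  p <- as.numeric(freqs)
  q <- 1 - p
  poly <- p > 0 & p < 1
  n <- nrow(dosages)
  # W = dosage - 2p; S by genotype class
  W <- dosages - rep(2 * p, each = n)
  het <- dosages == 1L
  hom2 <- dosages == 2L
  S <- matrix(rep(-2 * p^2, each = n), n, ncol(dosages))
  S[het] <- rep(2 * p * q, each = n)[het]
  S[hom2] <- rep(-2 * q^2, each = n)[hom2]
  if (any(!poly)) {
    W[, !poly] <- 0
    S[, !poly] <- 0
  }
  list(W = W, S = S, freqs = p, polymorphic = poly)
}

#' Additive and dominance genomic relationship matrices
#'
#' `Ga = W W' / sum(2 p q)` and `Gd = S S' / sum((2 p q)^2)`, with the
#' denominators taken over polymorphic markers only.
#'
#' @param coding Output of [code_markers()] (or a list with `W`, `S`,
#'   `freqs`, `polymorphic`).
#' @return List with `Ga`, `Gd`, and the denominators `sum2pq` and
#'   `sum2pq_sq`.
#' @export
build_grm <- function(coding) {
  p <- coding$freqs[coding$polymorphic]
  if (length(p) == 0L)
    stop("degenerate input: all markers are monomorphic")
  q <- 1 - p
  sum2pq <- sum(2 * p * q)
  sum2pq_sq <- sum((2 * p * q)^2)
  list(Ga = tcrossprod(coding$W) / sum2pq,
       Gd = tcrossprod(coding$S) / sum2pq_sq,
       sum2pq = sum2pq, sum2pq_sq = sum2pq_sq)
}

# Restricted log-likelihood (and the pieces reused by the REML updates)
# for y = 1 b + ua + ud + e at the given variance components.
.reml_pieces <- function(y, Ga, Gd, s2a, s2d, s2e) {
  n <- length(y)
  V <- s2a * Ga + s2d * Gd + diag(s2e, n)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Vinv <- chol2inv(R)
  vx <- rowSums(Vinv)            # Vinv %*% 1
  xvx <- sum(vx)
  vy <- drop(Vinv %*% y)
  Py <- vy - vx * (sum(vx * y) / xvx)
  # P = Vinv - vx vx^T / xvx (projection for the single intercept)
  logdetV <- 2 * sum(log(diag(R)))
  ll <- -0.5 * (logdetV + log(xvx) + sum(y * Py))
  list(ll = ll, Vinv = Vinv, vx = vx, xvx = xvx, Py = Py)
}

#' Fit variance components of the additive-dominance G-BLUP model by REML
#'
#' Maximises the restricted likelihood of
#' `y = 1 b + ua + ud + e`, `ua ~ N(0, Ga sigma2_a)`,
#' `ud ~ N(0, Gd sigma2_d)`, `e ~ N(0, I sigma2_e)`.
#'
#' The maximiser is an average-information (AI) Newton scheme guarded by
#' EM-REML steps: whenever the AI step would decrease the restricted
#' log-likelihood or leave the parameter space, the monotone EM update is
#' taken instead, so the log-likelihood trace is non-decreasing. The
#' first step is always an EM step. Components are floored at
#' `1e-8 * var(y)`.
#'
#' @param y Phenotype vector (one record per individual; the incidence
#'   of genetic effects is the identity).
#' @param Ga,Gd Genomic relationship matrices from [build_grm()].
#' @param tol Convergence tolerance on the relative change of each
#'   component (default 1e-6).
#' @param max_iter Maximum number of iterations (default 500).
#' @param init Optional starting values `c(sigma2_a, sigma2_d, sigma2_e)`
#'   (e.g. estimates from a related fit); defaults to an equal split of
#'   the phenotypic variance.
#' @return List with `sigma2_a`, `sigma2_d`, `sigma2_e`, `loglik`,
#'   `loglik_trace`, `iterations`, `converged`, and the internals `Py`,
#'   `Vinv` reused by [solve_effects()].
#' @export
reml_fit <- function(y, Ga, Gd, tol = 1e-6, max_iter = 500L, init = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n != nrow(Ga) || n != nrow(Gd))
    stop("phenotype length must equal the order of the relationship matrices")
  vp <- stats::var(y)
  if (!is.finite(vp) || vp <= 0) stop("phenotypes have zero variance")
  floor_v <- 1e-8 * vp
  theta <- if (is.null(init)) rep(vp / 3, 3L) else pmax(as.numeric(init), floor_v)

  G <- list(Ga, Gd)   # residual handled analytically (Ge = I)
  pieces <- .reml_pieces(y, Ga, Gd, theta[1L], theta[2L], theta[3L])
  if (is.null(pieces)) stop("initial variance matrix is not positive definite")
  trace <- pieces$ll
  converged <- FALSE
  it <- 0L

  em_step <- function(theta, pieces) {
    Py <- pieces$Py
    P_tr <- function(Gi) sum(pieces$Vinv * Gi) -
      sum(pieces$vx * drop(Gi %*% pieces$vx)) / pieces$xvx
    upd <- numeric(3L)
    for (k in 1:2) {
      GPy <- drop(G[[k]] %*% Py)
      upd[k] <- theta[k] + theta[k]^2 * (sum(Py * GPy) - P_tr(G[[k]])) / n
    }
    trP <- sum(diag(pieces$Vinv)) - sum(pieces$vx^2) / pieces$xvx
    upd[3L] <- theta[3L] + theta[3L]^2 * (sum(Py * Py) - trP) / n
    pmax(upd, floor_v)
  }

  ai_step <- function(theta, pieces) {
    Py <- pieces$Py
    Papply <- function(v) drop(pieces$Vinv %*% v) -
      pieces$vx * (sum(pieces$vx * v) / pieces$xvx)
    t1 <- drop(G[[1L]] %*% Py); t2 <- drop(G[[2L]] %*% Py); t3 <- Py
    Pt <- list(Papply(t1), Papply(t2), Papply(t3))
    AI <- matrix(0, 3L, 3L)
    tv <- list(t1, t2, t3)
    for (i in 1:3) for (j in i:3)
      AI[i, j] <- AI[j, i] <- 0.5 * sum(tv[[i]] * Pt[[j]])
    P_tr <- function(Gi) sum(pieces$Vinv * Gi) -
      sum(pieces$vx * drop(Gi %*% pieces$vx)) / pieces$xvx
    trP <- sum(diag(pieces$Vinv)) - sum(pieces$vx^2) / pieces$xvx
    score <- 0.5 * c(sum(Py * t1) - P_tr(G[[1L]]),
                     sum(Py * t2) - P_tr(G[[2L]]),
                     sum(Py * t3) - trP)
    # components pinned at the floor with a negative gradient stay fixed,
    # otherwise their near-singular AI rows stall the Newton step
    free <- !(theta <= floor_v * 1.01 & score < 0)
    if (!any(free)) return(NULL)
    delta <- numeric(3L)
    d_free <- tryCatch(solve(AI[free, free, drop = FALSE], score[free]),
                       error = function(e) NULL)
    if (is.null(d_free)) return(NULL)
    delta[free] <- d_free
    pmax(theta + delta, floor_v)
  }

  for (it in seq_len(max_iter)) {
    cur_ll <- pieces$ll
    proposal <- if (it == 1L) NULL else ai_step(theta, pieces)
    accepted <- FALSE
    if (!is.null(proposal)) {
      cand <- .reml_pieces(y, Ga, Gd, proposal[1L], proposal[2L], proposal[3L])
      if (!is.null(cand) && cand$ll >= cur_ll - 1e-10) {
        new_theta <- proposal; new_pieces <- cand; accepted <- TRUE
      }
    }
    if (!accepted) {
      new_theta <- em_step(theta, pieces)
      cand <- .reml_pieces(y, Ga, Gd, new_theta[1L], new_theta[2L], new_theta[3L])
      if (is.null(cand)) break
      new_pieces <- cand
    }
    rel <- abs(new_theta - theta) / pmax(theta, floor_v)
    theta <- new_theta
    pieces <- new_pieces
    trace <- c(trace, pieces$ll)
    if (max(rel) < tol) { converged <- TRUE; break }
  }

  list(sigma2_a = theta[1L], sigma2_d = theta[2L], sigma2_e = theta[3L],
       loglik = pieces$ll, loglik_trace = trace,
       iterations = it, converged = converged,
       Py = pieces$Py, Vinv = pieces$Vinv,
       vx = pieces$vx, xvx = pieces$xvx, floor = floor_v)
}

#' Solve for marker effects
#'
#' Backsolves the additive and dominance marker effects of the
#' marker-level model equivalent to G-BLUP. Two routes are provided and
#' agree to numerical precision:
#' \describe{
#'   \item{`"backsolve"` (default)}{`ma = sigma2_ma W' P y`,
#'     `md = sigma2_md S' P y`, using the projection from the REML fit.}
#'   \item{`"mme"`}{direct solution of the marker-level ridge mixed-model
#'     equations with shrinkage `lambda_a = sigma2_e / sigma2_ma` and
#'     `lambda_d = sigma2_e / sigma2_md`.}
#' }
#' Here `sigma2_ma = sigma2_a / sum(2pq)` and
#' `sigma2_md = sigma2_d / sum((2pq)^2)` are the marker-level variances.
#'
#' @param y Training phenotypes.
#' @param coding Output of [code_markers()] for the training set.
#' @param grm Output of [build_grm()] for the same coding.
#' @param fit Output of [reml_fit()] (needed for `"backsolve"`), or a
#'   list with `sigma2_a`, `sigma2_d`, `sigma2_e` (enough for `"mme"`).
#' @param method `"backsolve"` or `"mme"`.
#' @return An object of class `marker_model`: per-marker `ma`, `md`,
#'   `intercept`, `training_freqs`, variance components (population- and
#'   marker-level), and fit metadata.
#' @export
solve_effects <- function(y, coding, grm, fit, method = c("backsolve", "mme")) {
  method <- match.arg(method)
  y <- as.numeric(y)
  s2ma <- fit$sigma2_a / grm$sum2pq
  s2md <- fit$sigma2_d / grm$sum2pq_sq
  if (method == "backsolve") {
    if (is.null(fit$Py)) stop("'backsolve' needs the projection from reml_fit()")
    ma <- unname(s2ma * drop(crossprod(coding$W, fit$Py)))
    md <- unname(s2md * drop(crossprod(coding$S, fit$Py)))
    intercept <- sum(fit$vx * y) / fit$xvx
  } else {
    lam_a <- fit$sigma2_e / s2ma
    lam_d <- fit$sigma2_e / s2md
    n <- length(y)
    p <- ncol(coding$W)
    Tm <- cbind(1, coding$W, coding$S)
    C <- crossprod(Tm)
    idx_a <- 1L + seq_len(p)
    idx_d <- 1L + p + seq_len(p)
    diag(C)[idx_a] <- diag(C)[idx_a] + lam_a
    diag(C)[idx_d] <- diag(C)[idx_d] + lam_d
    sol <- solve(C, crossprod(Tm, y))
    intercept <- sol[1L]
    ma <- sol[idx_a]
    md <- sol[idx_d]
  }
  structure(
    list(ma = ma, md = md, intercept = intercept,
         training_freqs = coding$freqs,
         polymorphic = coding$polymorphic,
         sigma2_a = fit$sigma2_a, sigma2_d = fit$sigma2_d,
         sigma2_e = fit$sigma2_e,
         sigma2_ma = s2ma, sigma2_md = s2md,
         sum2pq = grm$sum2pq, sum2pq_sq = grm$sum2pq_sq,
         converged = fit$converged, iterations = fit$iterations,
         loglik = fit$loglik),
    class = "marker_model")
}

#' @export
print.marker_model <- function(x, ...) {
  cat(sprintf(paste0(
    "Additive-dominance marker model: %d markers (%d polymorphic)\n",
    "  sigma2_a = %.4f, sigma2_d = %.4f, sigma2_e = %.4f\n",
    "  REML: %d iterations, converged = %s, logL = %.3f\n"),
    length(x$ma), sum(x$polymorphic),
    x$sigma2_a, x$sigma2_d, x$sigma2_e,
    x$iterations, x$converged, x$loglik))
  invisible(x)
}

#' Predict total genomic values for new individuals
#'
#' Codes the validation dosages with the *training* allele frequencies
#' stored in the model and returns `W ma + S md` (intercept-free: the
#' intercept cancels in every correlation-based reliability).
#'
#' @param object A `marker_model`.
#' @param newdata A `population` or a dosage matrix aligned to the
#'   training marker order.
#' @param ... Unused.
#' @return Numeric vector of predicted total genomic values.
#' @export
predict.marker_model <- function(object, newdata, ...) {
  d <- if (inherits(newdata, "population")) dosages(newdata) else as.matrix(newdata)
  if (ncol(d) != length(object$ma))
    stop("marker count mismatch between model and validation data")
  coding <- code_markers(d, object$training_freqs)
  drop(coding$W %*% object$ma + coding$S %*% object$md)
}

#' Train an additive-dominance G-BLUP model
#'
#' Convenience wrapper: computes training allele frequencies, codes the
#' markers, builds the relationship matrices, fits the variance
#' components by REML and backsolves the marker effects.
#'
#' @param train A `population` or dosage matrix (training individuals).
#' @param y Training phenotypes (one per individual).
#' @param tol,max_iter,init Passed to [reml_fit()].
#' @param freqs Optional externally supplied coding frequencies
#'   (defaults to the observed training frequencies).
#' @return A `marker_model` (see [solve_effects()]); the REML fit is
#'   attached as attribute `"fit"` and the training GEBVs as `"gebv"`.
#' @export
gblup_train <- function(train, y, tol = 1e-6, max_iter = 500L,
                        init = NULL, freqs = NULL) {
  d <- if (inherits(train, "population")) dosages(train) else as.matrix(train)
  if (nrow(d) != length(y))
    stop("number of phenotypes must match number of individuals")
  if (is.null(freqs)) freqs <- colMeans(d) / 2
  coding <- code_markers(d, freqs)
  grm <- build_grm(coding)
  fit <- reml_fit(y, grm$Ga, grm$Gd, tol = tol, max_iter = max_iter, init = init)
  model <- solve_effects(y, coding, grm, fit)
  attr(model, "fit") <- fit
  attr(model, "gebv") <- drop(coding$W %*% model$ma + coding$S %*% model$md)
  model
}

#' Reliability of genomic prediction
#'
#' Squared Pearson correlation between predicted and true genetic
#' values.
#'
#' @param predicted Predicted genomic values.
#' @param true_values True genetic values, same length.
#' @return A single number in `[0, 1]`.
#' @export
reliability <- function(predicted, true_values) {
  if (length(predicted) != length(true_values))
    stop("'predicted' and 'true_values' must have equal length")
  if (stats::sd(predicted) == 0 || stats::sd(true_values) == 0)
    stop("undefined reliability: constant vector")
  stats::cor(predicted, true_values)^2
}
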