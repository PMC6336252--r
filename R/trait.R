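#' Binomial locus-contribution weights
#'
#' Locus weights proportional to the terms of the binomial expansion
#' `(1/2 + 1/2)^s`: `w_j = choose(s, j - 1) / 2^s` for `j = 1..s+1`.
#' With `s = 19` this yields the 20 QTL contributions used by the default
#' trait architecture; the weights sum to one and are symmetric.
#'
#' @param s Binomial exponent (locus count minus one, non-negative).
#' @return Numeric vector of `s + 1` weights summing to 1.
#' @examples
#' binomial_weights(19)[10]   # central weight, choose(19, 9) / 2^19
#' @export
binomial_weights <- function(s) {
  if (length(s) != 1L || !is.finite(s) || s < 0 || s != round(s))
    stop("'s' must be a single non-negative integer")
  stats::dbinom(0:s, size = s, prob = 0.5)
}

#' Place QTL on the map
#'
#' Deterministically places `per_group` QTL in each linkage group, at the
#' markers closest to the requested within-group positions (defaults
#' 25 cM and 75 cM, i.e. the two quartiles of a 100 cM group).
#'
#' @param map A `genetic_map`.
#' @param positions_cM Within-group target positions, one per QTL.
#' @return Integer vector of QTL marker indices in genome order
#'   (`length(positions_cM)` per group).
#' @export
assign_qtl <- function(map, positions_cM = c(25, 75)) {
  stopifnot(inherits(map, "genetic_map"))
  k <- length(positions_cM)
  if (map$markers_per_group < k)
    stop(sprintf("cannot place %d QTL in a group of %d marker(s)",
                 k, map$markers_per_group))
  idx <- integer(0)
  for (g in seq_len(map$group_count)) {
    in_g <- which(map$group == g)
    pos <- map$pos_cM[in_g]
    pick <- integer(k)
    for (j in seq_len(k)) {
      ord <- order(abs(pos - positions_cM[j]), pos)
      cand <- setdiff(in_g[ord], pick)
      pick[j] <- cand[1L]
    }
    idx <- c(idx, sort(pick))
  }
  idx
}

#' Define a quantitative-trait architecture
#'
#' The trait is controlled by QTL placed on the map (default: 2 per
#' linkage group, 20 in total). Locus `j` has additive effect
#' `a_j = w_j * additive_unit` where `w_j` are the binomial weights, and
#' dominance effect `d_j = dominance_ratio * a_j`.
#'
#' @param map A `genetic_map`.
#' @param dominance_ratio Degree of dominance d/a (0 = purely additive,
#'   1 = complete dominance). Any non-negative real.
#' @param mu Trait baseline (cancels in every downstream correlation).
#' @param additive_unit Homozygote effect scale `a` (default 1, so the
#'   favourable homozygote scores +1, the heterozygote 0 and the other
#'   homozygote -1 before weighting).
#' @param qtl_indices Marker indices of the QTL (default [assign_qtl()]).
#' @return An object of class `trait_architecture` with fields
#'   `qtl_indices`, `weights`, `add_effects`, `dom_effects`,
#'   `dominance_ratio`, `mu`, `additive_unit`.
#' @export
trait_architecture <- function(map, dominance_ratio = 0, mu = 0,
                               additive_unit = 1,
                               qtl_indices = assign_qtl(map)) {
  stopifnot(inherits(map, "genetic_map"))
  if (length(dominance_ratio) != 1L || dominance_ratio < 0)
    stop("'dominance_ratio' must be a single non-negative number")
  w <- binomial_weights(length(qtl_indices) - 1L)
  structure(
    list(qtl_indices = as.integer(qtl_indices),
         weights = w,
         add_effects = w * additive_unit,
         dom_effects = dominance_ratio * w * additive_unit,
         dominance_ratio = dominance_ratio,
         mu = mu,
         additive_unit = additive_unit),
    class = "trait_architecture")
}

#' True genetic values
#'
#' `G_i = mu + sum_j a_j * score_ij + sum_j d_j * het_ij`, where
#' `score_ij` is +1/0/-1 for QTL dosage 2/1/0 and `het_ij` indicates the
#' heterozygote.
#'
#' @param x A `population`, or a dosage matrix (individuals x markers, or
#'   individuals x QTL when it has exactly as many columns as QTL).
#' @param architecture A `trait_architecture`.
#' @return Numeric vector of true genetic values, one per individual.
#' @export
genetic_value <- function(x, architecture) {
  stopifnot(inherits(architecture, "trait_architecture"))
  d <- if (inherits(x, "population")) dosages(x) else as.matrix(x)
  q <- length(architecture$qtl_indices)
  Q <- if (ncol(d) == q) d else d[, architecture$qtl_indices, drop = FALSE]
  if (any(Q != 0L & Q != 1L & Q != 2L))
    stop("dosages must be 0, 1 or 2")
  score <- Q - 1
  het <- (Q == 1) + 0
  drop(architecture$mu + score %*% architecture$add_effects +
         het %*% architecture$dom_effects)
}

#' Genetic variance of the F2 base
#'
#' Either the empirical variance of the realised true genetic values in
#' an F2 population (default; this is the variance used to scale
#' environmental noise) or the closed-form F2 expectation
#' `sum_j (a_j^2 / 2 + d_j^2 / 4)` at allele frequency 1/2 under linkage
#' equilibrium, provided for comparison.
#'
#' @param architecture A `trait_architecture`.
#' @param population An F2 `population` (required for the empirical
#'   method; at least 2 individuals).
#' @param method `"empirical"` or `"closed_form"`.
#' @return The genetic variance (single number).
#' @export
genetic_variance_f2 <- function(architecture, population = NULL,
                                method = c("empirical", "closed_form")) {
  method <- match.arg(method)
  if (method == "closed_form")
    return(sum(architecture$add_effects^2 / 2 + architecture$dom_effects^2 / 4))
  if (is.null(population) || pop_size(population) < 2L)
    stop("empirical genetic variance needs a population of at least 2")
  stats::var(genetic_value(population, architecture))
}

#' Environmental variance for a target heritability
#'
#' `sigma2_e = sigma2_g * (1 - h2) / h2`.
#'
#' @param sigma2_g Genetic variance (positive).
#' @param h2 Target broad-sense heritability, strictly between 0 and 1.
#' @return Environmental variance.
#' @export
environmental_variance <- function(sigma2_g, h2) {
  if (length(h2) != 1L || !is.finite(h2) || h2 <= 0 || h2 >= 1)
    stop("'h2' must lie strictly between 0 and 1")
  if (length(sigma2_g) != 1L || !is.finite(sigma2_g) || sigma2_g <= 0)
    stop("'sigma2_g' must be positive")
  sigma2_g * (1 - h2) / h2
}

#' Simulate phenotypes
#'
#' `P_i = G_i + E_i` with `E_i ~ Normal(0, sigma2_e)` independent across
#' individuals. When `sigma2_e` is not supplied it is derived from the
#' empirical genetic variance of this population and the target `h2`; in
#' the multigeneration pipeline `sigma2_e` is computed once from the F2
#' of the replicate and held fixed for all descendant generations, so the
#' heritability is defined in the base population and the environment
#' does not change across generations.
#'
#' @param population A `population`.
#' @param architecture A `trait_architecture`.
#' @param h2 Target broad-sense heritability (ignored when `sigma2_e`
#'   is given).
#' @param sigma2_e Environmental variance; may be 0 to obtain noise-free
#'   phenotypes.
#' @return An object of class `phenotype_set`: list with `G`, `E`, `P`
#'   (numeric vectors), `sigma2_g` (empirical, this population),
#'   `sigma2_e`, and `generation`.
#' @export
simulate_phenotypes <- function(population, architecture, h2 = NULL,
                                sigma2_e = NULL) {
  G <- genetic_value(population, architecture)
  if (is.null(sigma2_e)) {
    if (is.null(h2)) stop("supply either 'h2' or 'sigma2_e'")
    sigma2_e <- environmental_variance(stats::var(G), h2)
  }
  if (sigma2_e < 0) stop("'sigma2_e' must be non-negative")
  E <- stats::rnorm(length(G), 0, sqrt(sigma2_e))
  structure(list(G = G, E = E, P = G + E,
                 sigma2_g = stats::var(G), sigma2_e = sigma2_e,
                 generation = population$generation),
            class = "phenotype_set")
}

#' @export
print.phenotype_set <- function(x, ...) {
  cat(sprintf("Phenotypes (%s): n = %d, var(G) = %.4f, sigma2_e = %.4f, realized h2 = %.3f\n",
              x$generation, length(x$P), x$sigma2_g, x$sigma2_e,
              x$sigma2_g / stats::var(x$P)))
  invisible(x)
}
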