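#' Gamete (haplotype) matrix of a population
#'
#' @param population A `population`.
#' @return Integer matrix (2N x markers) stacking both haplotypes of
#'   every individual: the observed gamete pool.
#' @export
haplotype_matrix <- function(population) {
  rbind(population$h1, population$h2)
}

#' Linkage disequilibrium between two loci from phased haplotypes
#'
#' `D = f(AB) - f(A) f(B)` over the observed gamete pool, and
#' `r2 = D^2 / (pA qA pB qB)`.
#'
#' @param haplotypes A `population` or a haplotype (gamete) matrix with
#'   0/1 alleles, one gamete per row.
#' @param locusA,locusB Marker column indices.
#' @return List with `D` and `r2`. Both are `NA` when either locus is
#'   monomorphic in the gamete pool (undefined LD; such pairs are
#'   skipped in summaries).
#' @export
r2_from_haplotypes <- function(haplotypes, locusA, locusB) {
  H <- if (inherits(haplotypes, "population")) haplotype_matrix(haplotypes)
       else as.matrix(haplotypes)
  a <- H[, locusA]; b <- H[, locusB]
  pA <- mean(a); pB <- mean(b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    return(list(D = NA_real_, r2 = NA_real_))
  D <- mean(a * b) - pA * pB
  list(D = D, r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

#' Maximum-likelihood LD from unphased genotypes (EM)
#'
#' Estimates the two-locus haplotype frequencies from genotype dosages by
#' the EM algorithm, resolving the phase ambiguity of double
#' heterozygotes, and returns the ML gametic disequilibrium `D` and
#' `r2`. With no double heterozygotes the estimate equals the
#' phase-known estimator exactly.
#'
#' @param dosagesA,dosagesB Genotype dosages (0/1/2) at the two loci for
#'   the same individuals.
#' @param tol Convergence tolerance on haplotype frequencies
#'   (default 1e-8).
#' @param max_iter Iteration cap (default 1000).
#' @return List with `D`, `r2`, `haplotype_freqs` (f11, f10, f01, f00),
#'   `iterations`, `converged`.
#' @export
r2_em_unphased <- function(dosagesA, dosagesB, tol = 1e-8, max_iter = 1000L) {
  gA <- as.integer(dosagesA); gB <- as.integer(dosagesB)
  if (length(gA) != length(gB)) stop("dosage vectors must have equal length")
  if (any(c(gA, gB) < 0L | c(gA, gB) > 2L)) stop("dosages must be 0, 1 or 2")
  n <- length(gA)
  pA <- mean(gA) / 2; pB <- mean(gB) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    return(list(D = NA_real_, r2 = NA_real_, haplotype_freqs = NULL,
                iterations = 0L, converged = TRUE))
  # genotype-combination counts
  cnt <- table(factor(gA, 0:2), factor(gB, 0:2))
  dh <- cnt["1", "1"]  # double heterozygotes (phase-ambiguous)
  # fixed haplotype counts from unambiguous genotypes
  base11 <- 2 * cnt["2", "2"] + cnt["2", "1"] + cnt["1", "2"]
  base10 <- 2 * cnt["2", "0"] + cnt["2", "1"] + cnt["1", "0"]
  base01 <- 2 * cnt["0", "2"] + cnt["0", "1"] + cnt["1", "2"]
  base00 <- 2 * cnt["0", "0"] + cnt["0", "1"] + cnt["1", "0"]
  f <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    num <- f[1L] * f[4L]
    den <- num + f[2L] * f[3L]
    pc <- if (den > 0) num / den else 0.5  # P(coupling | double het)
    f_new <- c(base11 + dh * pc,
               base10 + dh * (1 - pc),
               base01 + dh * (1 - pc),
               base00 + dh * pc) / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  pA_hat <- f[1L] + f[2L]; pB_hat <- f[1L] + f[3L]
  D <- f[1L] - pA_hat * pB_hat
  r2 <- D^2 / (pA_hat * (1 - pA_hat) * pB_hat * (1 - pB_hat))
  list(D = D, r2 = r2,
       haplotype_freqs = c(f11 = f[1L], f10 = f[2L], f01 = f[3L], f00 = f[4L]),
       iterations = it, converged = converged)
}

# all within-group pairwise r2 for one population; returns a data.frame
# (group, locusA, locusB, distance_cM, r2); monomorphic pairs dropped,
# their count attached as an attribute
.r2_pairs <- function(population, map, max_distance = Inf) {
  H <- haplotype_matrix(population)
  out <- vector("list", map$group_count)
  n_skipped <- 0L
  for (g in seq_len(map$group_count)) {
    in_g <- which(map$group == g)
    Hg <- H[, in_g, drop = FALSE]
    p <- colMeans(Hg)
    poly <- p > 0 & p < 1
    pos <- map$pos_cM[in_g]
    dist <- abs(outer(pos, pos, "-"))
    keep_pair <- upper.tri(dist) & dist <= max_distance
    poly_pair <- outer(poly, poly, "&")
    n_skipped <- n_skipped + sum(keep_pair & !poly_pair)
    keep_pair <- keep_pair & poly_pair
    if (!any(keep_pair)) { out[[g]] <- NULL; next }
    r2 <- suppressWarnings(stats::cor(Hg)^2)
    ij <- which(keep_pair, arr.ind = TRUE)
    out[[g]] <- data.frame(group = g,
                           locusA = in_g[ij[, 1L]],
                           locusB = in_g[ij[, 2L]],
                           distance_cM = dist[keep_pair],
                           r2 = r2[keep_pair])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(group = integer(), locusA = integer(),
                      locusB = integer(), distance_cM = numeric(),
                      r2 = numeric())
  attr(res, "n_monomorphic_pairs") <- n_skipped
  res
}

#' Summarise LD decay across generations
#'
#' Computes pairwise `r2` from phased haplotypes for all within-group
#' marker pairs up to `max_distance`, for each population in a series,
#' and summarises the mean `r2` per map-distance bin. Inter-group pairs
#' are excluded (LD is assessed within each linkage group separately);
#' pairs involving a monomorphic locus are skipped and counted.
#'
#' @param population_series A named list of `population`s (e.g. from
#'   [simulate_series()]).
#' @param map The shared `genetic_map`.
#' @param max_distance Largest pair distance (cM) to include; 0 yields an
#'   empty table.
#' @param bin_width Width (cM) of the distance bins (default: the map
#'   spacing, so the first bin holds adjacent pairs).
#' @return A data.frame with columns `generation`, `distance_bin_cM`
#'   (upper edge), `n_pairs`, `mean_r2`, plus attributes
#'   `adjacent_mean_r2` (named per generation, mean over pairs at the
#'   adjacency distance), `overall_mean_r2`, and `n_monomorphic_pairs`.
#' @export
ld_decay_table <- function(population_series, map, max_distance = Inf,
                           bin_width = map$spacing) {
  stopifnot(inherits(map, "genetic_map"))
  if (inherits(population_series, "population"))
    population_series <- stats::setNames(list(population_series),
                                         population_series$generation)
  rows <- list()
  adj <- numeric(0)
  overall <- numeric(0)
  skipped <- 0L
  for (nm in names(population_series)) {
    pairs <- .r2_pairs(population_series[[nm]], map, max_distance)
    skipped <- skipped + attr(pairs, "n_monomorphic_pairs")
    if (nrow(pairs) == 0L) next
    bin <- ceiling(pairs$distance_cM / bin_width) * bin_width
    agg <- stats::aggregate(pairs$r2, list(distance_bin_cM = bin),
                            function(v) c(n = length(v), m = mean(v)))
    rows[[nm]] <- data.frame(generation = nm,
                             distance_bin_cM = agg$distance_bin_cM,
                             n_pairs = agg$x[, "n"],
                             mean_r2 = agg$x[, "m"])
    is_adj <- abs(pairs$distance_cM - map$spacing) < 1e-9
    adj[nm] <- if (any(is_adj)) mean(pairs$r2[is_adj]) else NA_real_
    overall[nm] <- mean(pairs$r2)
  }
  res <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else data.frame(generation = character(), distance_bin_cM = numeric(),
                         n_pairs = numeric(), mean_r2 = numeric())
  attr(res, "adjacent_mean_r2") <- adj
  attr(res, "overall_mean_r2") <- overall
  attr(res, "n_monomorphic_pairs") <- skipped
  res
}

#' Pairwise r2 matrix of one linkage group (heatmap export)
#'
#' @param population A `population`.
#' @param map The `genetic_map`.
#' @param group Linkage-group index.
#' @return Symmetric matrix of pairwise `r2` among the group's markers
#'   (`NA` rows/columns for monomorphic loci), suitable for heatmap
#'   rendering or CSV export.
#' @export
r2_heatmap_matrix <- function(population, map, group = 1L) {
  in_g <- which(map$group == group)
  H <- haplotype_matrix(population)[, in_g, drop = FALSE]
  R2 <- suppressWarnings(stats::cor(H)^2)
  dimnames(R2) <- list(map$marker_ids[in_g], map$marker_ids[in_g])
  R2
}
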