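#' Construct a population of phased diploid genotypes
#'
#' @param h1,h2 Integer matrices (individuals x markers) of 0/1 alleles,
#'   one row per individual, giving the two haplotypes of each individual.
#'   Haplotype order within an individual carries no meaning.
#' @param generation Generation label, e.g. `"F2"`, `"S1"`, `"A3"`, `"Bc2"`.
#' @param system Mating system that produced the population: one of
#'   `"base"`, `"selfing"`, `"random_mating"`, `"backcross"`.
#' @param gen_index Number of advancement generations since the F2 base
#'   (0 for the F2 itself).
#' @return An object of class `population`.
#' @export
new_population <- function(h1, h2, generation = "F2", system = "base",
                           gen_index = 0L) {
  h1 <- as.matrix(h1); h2 <- as.matrix(h2)
  if (!identical(dim(h1), dim(h2)))
    stop("haplotype matrices must have identical dimensions")
  if (any(h1 != 0L & h1 != 1L) || any(h2 != 0L & h2 != 1L))
    stop("alleles must be coded 0/1")
  storage.mode(h1) <- "integer"
  storage.mode(h2) <- "integer"
  structure(list(h1 = h1, h2 = h2, generation = generation,
                 system = system, gen_index = as.integer(gen_index)),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("Population %s (%s): %d individuals x %d markers, mean H = %.3f\n",
              x$generation, x$system, nrow(x$h1), ncol(x$h1),
              mean(heterozygosity(x))))
  invisible(x)
}

#' Population size
#' @param population A `population`.
#' @return Number of individuals.
#' @export
pop_size <- function(population) nrow(population$h1)

#' Genotype dosage matrix
#'
#' @param population A `population`.
#' @return Integer matrix (individuals x markers) of allele-1 counts,
#'   values in 0/1/2.
#' @export
dosages <- function(population) population$h1 + population$h2

#' Per-locus allele frequency
#' @param population A `population`.
#' @return Numeric vector of allele-1 frequencies per marker.
#' @export
allele_freqs <- function(population) colMeans(dosages(population)) / 2

#' Per-locus observed heterozygosity
#' @param population A `population`.
#' @return Numeric vector of per-marker heterozygote frequencies.
#' @export
heterozygosity <- function(population) colMeans(population$h1 != population$h2)

#' Simulate the two fully divergent inbred founders
#'
#' Founder 1 is homozygous for allele 1 at every locus and founder 2 is
#' homozygous for allele 0, so the lines are maximally divergent and
#' their F1 is heterozygous at every marker.
#'
#' @param map A `genetic_map`.
#' @return A list with `parent1` and `parent2`, each a size-1 `population`.
#' @export
make_founders <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  m <- map$n_markers
  ones <- matrix(1L, 1L, m, dimnames = list(NULL, map$marker_ids))
  zeros <- matrix(0L, 1L, m, dimnames = list(NULL, map$marker_ids))
  list(parent1 = new_population(ones, ones, "P1", "base"),
       parent2 = new_population(zeros, zeros, "P2", "base"))
}

# Vectorised meiosis: one gamete per row of (h1, h2). The source
# haplotype switches between adjacent within-group markers with the
# Haldane recombination fraction for the map spacing; each linkage group
# starts from either haplotype with probability 1/2 (free recombination
# between groups), which is implemented as a switch probability of 1/2 at
# group boundaries so a single cumulative-XOR scan covers the genome.
.gametes <- function(h1, h2, map) {
  n <- nrow(h1); m <- ncol(h1)
  cfrac <- recombination_fraction(map$spacing)
  pr <- rep(cfrac, m)
  pr[match(unique(map$group), map$group)] <- 0.5
  switches <- matrix(stats::rbinom(n * m, 1L, rep(pr, each = n)), n, m)
  chooser <- t(apply(switches, 1L, cumsum)) %% 2L
  g <- h1 + (h2 - h1) * chooser
  storage.mode(g) <- "integer"
  g
}

#' Draw one gamete from an individual
#'
#' Meiosis with Haldane (no-interference) recombination between adjacent
#' markers within a linkage group and free recombination between groups.
#'
#' @param population A `population`.
#' @param map The `genetic_map` the population is aligned to.
#' @param individual Row index of the parent individual.
#' @return An integer 0/1 vector of length `map$n_markers`.
#' @export
make_gamete <- function(population, map, individual = 1L) {
  stopifnot(inherits(population, "population"), inherits(map, "genetic_map"))
  drop(.gametes(population$h1[individual, , drop = FALSE],
                population$h2[individual, , drop = FALSE], map))
}

#' Create the all-heterozygous F1 from the two divergent founders
#'
#' @param map A `genetic_map`.
#' @param n Number of (identical) F1 individuals to instantiate.
#' @return A `population` heterozygous at every marker with known phase
#'   (haplotype 1 all allele 1, haplotype 2 all allele 0).
#' @export
make_f1 <- function(map, n = 1L) {
  m <- map$n_markers
  new_population(matrix(1L, n, m), matrix(0L, n, m), "F1", "base")
}

#' Simulate the F2 base population
#'
#' Each F2 individual is the union of two independent F1 gametes. The
#' founders must be fully homozygous and divergent, so every F2 locus has
#' expected allele frequency 0.5 and expected heterozygosity 0.5, and all
#' linkage disequilibrium arises from physical linkage.
#'
#' @param parent1,parent2 Size-1 homozygous, divergent `population`s
#'   (see [make_founders()]).
#' @param n F2 population size (at least 2).
#' @param map A `genetic_map`.
#' @return A `population` labelled `"F2"`, system `"base"`.
#' @export
make_f2 <- function(parent1, parent2, n, map) {
  stopifnot(inherits(map, "genetic_map"))
  if (n < 2) stop("invalid configuration: F2 size 'n' must be at least 2")
  het1 <- population_is_homozygous(parent1)
  het2 <- population_is_homozygous(parent2)
  if (!het1 || !het2 || any(parent1$h1[1L, ] == parent2$h1[1L, ]))
    stop("parents must be fully homozygous and divergent at every locus")
  f1 <- new_population(parent1$h1[1L, , drop = FALSE],
                       parent2$h1[1L, , drop = FALSE], "F1", "base")
  rows <- matrix(1L, n, 1L)
  g1 <- .gametes(f1$h1[rows, , drop = FALSE], f1$h2[rows, , drop = FALSE], map)
  g2 <- .gametes(f1$h1[rows, , drop = FALSE], f1$h2[rows, , drop = FALSE], map)
  new_population(g1, g2, "F2", "base", gen_index = 0L)
}

population_is_homozygous <- function(population) {
  all(population$h1 == population$h2)
}

#' Advance a population by one generation
#'
#' @param population The current `population`.
#' @param system Mating system: `"selfing"` (each individual contributes
#'   exactly one selfed offspring, keeping census size constant),
#'   `"random_mating"` (each offspring from two distinct parents drawn
#'   uniformly with replacement), or `"backcross"` (one gamete from a
#'   randomly drawn parent crossed to one gamete from the recurrent
#'   parent).
#' @param map The `genetic_map`.
#' @param mode Random-mating implementation. `"meiosis"` (default) is
#'   standard sexual reproduction and preserves linkage disequilibrium up
#'   to one round of recombination. `"allele_resampling"` draws each
#'   offspring haplotype locus-by-locus from Bernoulli(current allele
#'   frequency), which destroys inter-locus disequilibrium in a single
#'   generation; it emulates breeding simulators whose advancement
#'   resamples alleles locus-wise, collapsing outcrossing LD at once.
#' @param recurrent Backcross recurrent parent: `"f1"` (default; the
#'   all-heterozygous F1 with known phase), `"parent1"` or `"parent2"`
#'   (the inbred founders).
#' @return The offspring `population`, same size, generation label
#'   advanced (S/A/Bc prefix by system).
#' @export
advance <- function(population,
                    system = c("selfing", "random_mating", "backcross"),
                    map,
                    mode = c("meiosis", "allele_resampling"),
                    recurrent = c("f1", "parent1", "parent2")) {
  stopifnot(inherits(population, "population"), inherits(map, "genetic_map"))
  system <- match.arg(system)
  mode <- match.arg(mode)
  recurrent <- match.arg(recurrent)
  n <- pop_size(population)
  if (n < 1L) stop("cannot advance an empty population")
  m <- map$n_markers
  if (ncol(population$h1) != m)
    stop("population and map disagree on marker count")

  if (system == "selfing") {
    g1 <- .gametes(population$h1, population$h2, map)
    g2 <- .gametes(population$h1, population$h2, map)
  } else if (system == "random_mating") {
    if (mode == "allele_resampling") {
      p <- allele_freqs(population)
      g1 <- matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m)
      g2 <- matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m)
    } else {
      if (n < 2L) stop("random mating needs at least 2 individuals")
      mothers <- sample.int(n, n, replace = TRUE)
      fathers <- sample.int(n, n, replace = TRUE)
      repeat {
        clash <- fathers == mothers
        if (!any(clash)) break
        fathers[clash] <- sample.int(n, sum(clash), replace = TRUE)
      }
      g1 <- .gametes(population$h1[mothers, , drop = FALSE],
                     population$h2[mothers, , drop = FALSE], map)
      g2 <- .gametes(population$h1[fathers, , drop = FALSE],
                     population$h2[fathers, , drop = FALSE], map)
    }
  } else {  # backcross
    donors <- sample.int(n, n, replace = TRUE)
    g1 <- .gametes(population$h1[donors, , drop = FALSE],
                   population$h2[donors, , drop = FALSE], map)
    rec <- switch(recurrent,
                  f1 = make_f1(map, n),
                  parent1 = {
                    f <- make_founders(map)$parent1
                    new_population(f$h1[rep(1L, n), , drop = FALSE],
                                   f$h2[rep(1L, n), , drop = FALSE],
                                   "P1", "base")
                  },
                  parent2 = {
                    f <- make_founders(map)$parent2
                    new_population(f$h1[rep(1L, n), , drop = FALSE],
                                   f$h2[rep(1L, n), , drop = FALSE],
                                   "P2", "base")
                  })
    g2 <- .gametes(rec$h1, rec$h2, map)
  }

  t_next <- population$gen_index + 1L
  prefix <- switch(system, selfing = "S", random_mating = "A", backcross = "Bc")
  new_population(g1, g2, paste0(prefix, t_next), system, gen_index = t_next)
}

#' Simulate a full advancement series from an F2 base
#'
#' Builds the F2 and advances it `generations` times under one mating
#' system, returning every generation.
#'
#' @param map A `genetic_map`.
#' @param n Population size (constant across generations).
#' @param system Mating system passed to [advance()].
#' @param generations Number of advancement generations (default 4).
#' @param mode,recurrent Passed to [advance()].
#' @param f2 Optionally, an existing F2 `population` to advance (so the
#'   same base can feed several systems); simulated if `NULL`.
#' @return A named list of `population`s: `F2`, then e.g. `S1`..`S4`.
#' @export
simulate_series <- function(map, n = 500L,
                            system = c("selfing", "random_mating", "backcross"),
                            generations = 4L,
                            mode = c("meiosis", "allele_resampling"),
                            recurrent = c("f1", "parent1", "parent2"),
                            f2 = NULL) {
  system <- match.arg(system)
  mode <- match.arg(mode)
  recurrent <- match.arg(recurrent)
  if (is.null(f2)) {
    founders <- make_founders(map)
    f2 <- make_f2(founders$parent1, founders$parent2, n, map)
  }
  out <- vector("list", generations + 1L)
  names(out) <- c("F2", character(generations))
  out[["F2"]] <- f2
  cur <- f2
  for (t in seq_len(generations)) {
    cur <- advance(cur, system, map, mode = mode, recurrent = recurrent)
    names(out)[t + 1L] <- cur$generation
    out[[t + 1L]] <- cur
  }
  out
}
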