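#' Define the scenario grid of the simulation study
#'
#' Bundles every knob of the multigeneration study: genome, base
#' population size, genetic architectures (degrees of dominance x
#' heritabilities), mating systems, advancement depth, replicate count
#' and master seed.
#'
#' @param dominance_ratios Degrees of dominance d/a (default 0, 0.5, 1).
#' @param heritabilities Broad-sense heritabilities (default 0.30, 0.70).
#' @param systems Mating systems to advance the F2 under.
#' @param generations Advancement generations per system (default 4).
#' @param replicates Number of simulation replicates (default 10).
#' @param n Population size of the F2 and of every advanced generation.
#' @param map A `genetic_map` (default [build_map()]).
#' @param random_mating_mode `"allele_resampling"` (default here: the
#'   study's outcrossing series is defined by a one-generation LD
#'   collapse) or `"meiosis"` (the biologically standard choice; see
#'   [advance()]).
#' @param recurrent Backcross recurrent parent (default `"f1"`).
#' @param qtl_positions_cM Within-group QTL positions
#'   (see [assign_qtl()]).
#' @param master_seed Master seed; all simulation streams are derived
#'   from it with [derive_seed()].
#' @return An object of class `scenario_grid`.
#' @export
scenario_grid <- function(dominance_ratios = c(0, 0.5, 1),
                          heritabilities = c(0.30, 0.70),
                          systems = c("selfing", "random_mating", "backcross"),
                          generations = 4L,
                          replicates = 10L,
                          n = 500L,
                          map = build_map(),
                          random_mating_mode = c("allele_resampling", "meiosis"),
                          recurrent = c("f1", "parent1", "parent2"),
                          qtl_positions_cM = c(25, 75),
                          master_seed = 1L) {
  systems <- match.arg(systems, several.ok = TRUE)
  random_mating_mode <- match.arg(random_mating_mode)
  recurrent <- match.arg(recurrent)
  if (any(heritabilities <= 0 | heritabilities >= 1))
    stop("'heritabilities' must lie strictly between 0 and 1")
  if (any(dominance_ratios < 0))
    stop("'dominance_ratios' must be non-negative")
  if (replicates < 1L) stop("'replicates' must be at least 1")
  structure(
    list(dominance_ratios = dominance_ratios,
         heritabilities = heritabilities,
         systems = systems,
         generations = as.integer(generations),
         replicates = as.integer(replicates),
         n = as.integer(n),
         map = map,
         random_mating_mode = random_mating_mode,
         recurrent = recurrent,
         qtl_positions_cM = qtl_positions_cM,
         master_seed = as.integer(master_seed)),
    class = "scenario_grid")
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat(sprintf(paste0(
    "Scenario grid: %d architecture(s) (d/a in {%s} x h2 in {%s}), ",
    "systems {%s}, %d generations, N = %d, %d replicate(s), seed %d\n"),
    length(x$dominance_ratios) * length(x$heritabilities),
    paste(x$dominance_ratios, collapse = ", "),
    paste(x$heritabilities, collapse = ", "),
    paste(x$systems, collapse = ", "),
    x$generations, x$n, x$replicates, x$master_seed))
  invisible(x)
}

# Simulate the shared genomes of one (replicate, dominance) cell: one F2
# base advanced under every system in the grid, plus true genetic values.
.scenario_sim <- function(grid, replicate, dominance) {
  seed <- derive_seed(grid$master_seed, "replicate", replicate,
                      "dominance", round(100 * dominance), "genomes")
  set.seed(seed)
  map <- grid$map
  founders <- make_founders(map)
  f2 <- make_f2(founders$parent1, founders$parent2, grid$n, map)
  arch <- trait_architecture(map, dominance_ratio = dominance,
                             qtl_indices = assign_qtl(map, grid$qtl_positions_cM))
  pops <- list(F2 = f2)
  for (sys in grid$systems) {
    series <- simulate_series(map, grid$n, sys, grid$generations,
                              mode = grid$random_mating_mode,
                              recurrent = grid$recurrent, f2 = f2)
    pops[[sys]] <- series[-1L]  # F2 kept once at top level
  }
  G <- list(F2 = genetic_value(f2, arch))
  for (sys in grid$systems)
    G[[sys]] <- lapply(pops[[sys]], genetic_value, architecture = arch)
  list(map = map, arch = arch, pops = pops, G = G,
       sigma2_g_f2 = stats::var(G$F2), replicate = replicate,
       dominance = dominance)
}

# Phenotypes for every population of a simulated cell at one h2.
# sigma2_e is fixed from the F2 genetic variance of the replicate.
.scenario_phenotypes <- function(grid, sim, h2) {
  s2e <- environmental_variance(sim$sigma2_g_f2, h2)
  seed <- derive_seed(grid$master_seed, "replicate", sim$replicate,
                      "dominance", round(100 * sim$dominance),
                      "h2", round(100 * h2), "phenotypes")
  set.seed(seed)
  P <- list(F2 = sim$G$F2 + stats::rnorm(grid$n, 0, sqrt(s2e)))
  for (sys in grid$systems)
    P[[sys]] <- lapply(sim$G[[sys]], function(g)
      g + stats::rnorm(length(g), 0, sqrt(s2e)))
  list(P = P, sigma2_e = s2e)
}

.cell_row <- function(strategy, system, dominance, h2, replicate,
                      training, validation, n_train, rel) {
  data.frame(strategy = strategy, system = system, dominance = dominance,
             h2 = h2, replicate = replicate, training = training,
             validation = validation, n_train = n_train,
             reliability = rel)
}

#' Run the calibration strategies over a scenario grid
#'
#' Simulates each (replicate, dominance) cell once and evaluates the
#' requested calibration strategies on the shared populations, so
#' strategies are compared on identical genomes and phenotypes:
#' \describe{
#'   \item{Strategy 1}{train the additive-dominance G-BLUP on the F2;
#'     validate in-sample on the F2 and on every advanced generation of
#'     every system.}
#'   \item{Strategy 2}{for each system and each generation `n`, train on
#'     generation `n` and validate on generations `n..4` (the diagonal
#'     cells are in-sample).}
#'   \item{Strategy 3}{pool the F2 with the first `k` advanced
#'     generations (`k = 1, 2, 3`) as training sets of 1000/1500/2000 and
#'     validate each on generations `k..4`.}
#' }
#' Reliability is always the squared correlation between the predicted
#' total genomic value (additive + dominance, coded with training-set
#' allele frequencies) and the true genetic value of the validation
#' individuals.
#'
#' @param grid A `scenario_grid`.
#' @param strategies Subset of `c(1, 2, 3)`.
#' @param verbose Print progress lines.
#' @return A tidy data.frame with one row per (strategy, system,
#'   dominance, h2, replicate, training set, validation set):
#'   columns `strategy`, `system`, `dominance`, `h2`, `replicate`,
#'   `training`, `validation`, `n_train`, `reliability`.
#' @export
run_strategies <- function(grid, strategies = c(1L, 2L, 3L), verbose = FALSE) {
  stopifnot(inherits(grid, "scenario_grid"))
  strategies <- sort(unique(as.integer(strategies)))
  if (!all(strategies %in% 1:3)) stop("'strategies' must be a subset of 1:3")
  gens <- grid$generations
  out <- list()
  for (rep_i in seq_len(grid$replicates)) {
    for (dom in grid$dominance_ratios) {
      sim <- .scenario_sim(grid, rep_i, dom)
      for (h2 in grid$heritabilities) {
        ph <- .scenario_phenotypes(grid, sim, h2)
        if (verbose)
          message(sprintf("replicate %d, d/a = %g, h2 = %g", rep_i, dom, h2))

        if (1L %in% strategies) {
          mod <- gblup_train(sim$pops$F2, ph$P$F2)
          out[[length(out) + 1L]] <- .cell_row(
            1L, "base", dom, h2, rep_i, "F2", "F2", grid$n,
            reliability(attr(mod, "gebv"), sim$G$F2))
          for (sys in grid$systems) for (g in names(sim$pops[[sys]])) {
            out[[length(out) + 1L]] <- .cell_row(
              1L, sys, dom, h2, rep_i, "F2", g, grid$n,
              reliability(predict(mod, sim$pops[[sys]][[g]]), sim$G[[sys]][[g]]))
          }
        }

        if (2L %in% strategies) {
          for (sys in grid$systems) {
            labels <- names(sim$pops[[sys]])
            for (tr in seq_len(gens)) {
              mod <- gblup_train(sim$pops[[sys]][[tr]], ph$P[[sys]][[tr]])
              for (va in tr:gens) {
                rel <- if (va == tr) reliability(attr(mod, "gebv"),
                                                 sim$G[[sys]][[va]])
                       else reliability(predict(mod, sim$pops[[sys]][[va]]),
                                        sim$G[[sys]][[va]])
                out[[length(out) + 1L]] <- .cell_row(
                  2L, sys, dom, h2, rep_i, labels[tr], labels[va],
                  grid$n, rel)
              }
            }
          }
        }

        if (3L %in% strategies) {
          for (sys in grid$systems) {
            labels <- names(sim$pops[[sys]])
            init <- NULL
            pool_d <- dosages(sim$pops$F2)
            pool_y <- ph$P$F2
            for (k in seq_len(max(1L, gens - 1L))) {
              pool_d <- rbind(pool_d, dosages(sim$pops[[sys]][[k]]))
              pool_y <- c(pool_y, ph$P[[sys]][[k]])
              mod <- gblup_train(pool_d, pool_y, init = init)
              fit <- attr(mod, "fit")
              init <- c(fit$sigma2_a, fit$sigma2_d, fit$sigma2_e)
              training <- paste(c("F2", labels[seq_len(k)]), collapse = "+")
              for (va in k:gens) {
                out[[length(out) + 1L]] <- .cell_row(
                  3L, sys, dom, h2, rep_i, training, labels[va],
                  nrow(pool_d),
                  reliability(predict(mod, sim$pops[[sys]][[va]]),
                              sim$G[[sys]][[va]]))
              }
            }
          }
        }
      }
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' @rdname run_strategies
#' @export
run_strategy1 <- function(grid, verbose = FALSE)
  run_strategies(grid, 1L, verbose)

#' @rdname run_strategies
#' @export
run_strategy2 <- function(grid, verbose = FALSE)
  run_strategies(grid, 2L, verbose)

#' @rdname run_strategies
#' @export
run_strategy3 <- function(grid, verbose = FALSE)
  run_strategies(grid, 3L, verbose)

#' Aggregate replicate reliabilities into mean +/- SD cells
#'
#' @param results Tidy results from [run_strategies()].
#' @return A data.frame with one row per table cell: `strategy`,
#'   `system`, `dominance`, `h2`, `training`, `validation`,
#'   `n_replicates`, `mean`, `sd` (`NA` for a single replicate).
#' @export
aggregate_reliability <- function(results) {
  key <- c("strategy", "system", "dominance", "h2", "training", "validation")
  agg <- stats::aggregate(results$reliability, results[key], function(v)
    c(n = length(v), mean = mean(v),
      sd = if (length(v) > 1L) stats::sd(v) else NA_real_))
  out <- cbind(agg[key],
               n_replicates = agg$x[, "n"],
               mean = agg$x[, "mean"],
               sd = agg$x[, "sd"])
  out[order(out$strategy, out$system, out$dominance, out$h2,
            out$training, out$validation), , drop = FALSE]
}

#' Block average of reliability cells
#'
#' Mean reliability over a selected block of cells (e.g. the selfing
#' block of one strategy at one architecture), averaging first within
#' replicate across cells and then across replicates.
#'
#' @param results Tidy results from [run_strategies()].
#' @param strategy,system,dominance,h2 Filters; `NULL` keeps all levels.
#' @param exclude_f2_cell Drop the in-sample F2 validation cell of
#'   strategy 1 (so the block matches the per-system generation means).
#' @return A single mean reliability.
#' @export
block_average <- function(results, strategy = NULL, system = NULL,
                          dominance = NULL, h2 = NULL,
                          exclude_f2_cell = TRUE) {
  keep <- rep(TRUE, nrow(results))
  if (!is.null(strategy)) keep <- keep & results$strategy %in% strategy
  if (!is.null(system)) keep <- keep & results$system %in% system
  if (!is.null(dominance)) keep <- keep & results$dominance %in% dominance
  if (!is.null(h2)) keep <- keep & results$h2 %in% h2
  if (exclude_f2_cell) keep <- keep & results$validation != "F2"
  sub <- results[keep, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no cells match the requested block")
  per_rep <- tapply(sub$reliability, sub$replicate, mean)
  mean(per_rep)
}

#' Lay out strategy-1 aggregates in the wide study-table shape
#'
#' One row per (h2, dominance): the in-sample F2 column, then each
#' system's generations followed by the system's four-generation mean.
#'
#' @param agg Aggregated cells from [aggregate_reliability()] (strategy-1
#'   rows are used).
#' @return A wide data.frame of cell means.
#' @export
table1_layout <- function(agg) {
  agg <- agg[agg$strategy == 1L, , drop = FALSE]
  combos <- unique(agg[c("h2", "dominance")])
  combos <- combos[order(combos$h2, combos$dominance), , drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    a <- agg[agg$h2 == combos$h2[i] & agg$dominance == combos$dominance[i], ]
    row <- list(h2 = combos$h2[i], dominance = combos$dominance[i],
                F2 = a$mean[a$validation == "F2"])
    for (sys in setdiff(unique(a$system), "base")) {
      b <- a[a$system == sys, ]
      b <- b[order(b$validation), ]
      for (j in seq_len(nrow(b))) row[[b$validation[j]]] <- b$mean[j]
      prefix <- switch(sys, selfing = "S", random_mating = "A",
                       backcross = "Bc", sys)
      row[[paste0(prefix, "_mean")]] <- mean(b$mean)
    }
    as.data.frame(row)
  })
  do.call(rbind, rows)
}
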