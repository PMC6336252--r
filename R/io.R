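#' Default run configuration
#'
#' The default values are the study conditions: a 10 x 101 marker genome
#' at 1 cM spacing, an F2 of 500, four advancement generations under
#' three mating systems, six genetic architectures (d/a in {0, 0.5, 1} x
#' h2 in {0.30, 0.70}), 10 replicates.
#'
#' @return A named list of configuration values (see [load_config()]).
#' @export
default_config <- function() {
  list(group_count = 10L, markers_per_group = 101L, spacing = 1,
       population_size = 500L, generations = 4L,
       systems = c("selfing", "random_mating", "backcross"),
       dominance_ratios = c(0, 0.5, 1),
       heritabilities = c(0.30, 0.70),
       replicates = 10L,
       random_mating_mode = "allele_resampling",
       recurrent = "f1",
       qtl_positions_cM = c(25, 75),
       seed = 1L)
}

#' Load a run configuration from YAML or JSON
#'
#' Reads a configuration file, fills every absent key with the default
#' study settings (see [default_config()]), warns on unknown keys and
#' validates ranges. An empty file yields the full default
#' configuration.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::fromJSON(path)
         else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- default_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    warning("unknown configuration key(s) ignored: ",
            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, raw[intersect(names(raw), names(defaults))])
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk_pos_int <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stop(sprintf("invalid value for '%s': must be a positive integer", key))
  }
  for (k in c("group_count", "markers_per_group", "population_size", "generations",
              "replicates"))
    chk_pos_int(k)
  if (!is.numeric(cfg$spacing) || cfg$spacing <= 0)
    stop("invalid value for 'spacing': must be a positive map distance")
  if (any(cfg$heritabilities <= 0 | cfg$heritabilities >= 1))
    stop("invalid value for 'heritabilities': must lie strictly in (0, 1)")
  if (any(cfg$dominance_ratios < 0))
    stop("invalid value for 'dominance_ratios': must be non-negative")
  if (!all(cfg$systems %in% c("selfing", "random_mating", "backcross")))
    stop("invalid value for 'systems'")
  if (!cfg$random_mating_mode %in% c("allele_resampling", "meiosis"))
    stop("invalid value for 'random_mating_mode'")
  if (!cfg$recurrent %in% c("f1", "parent1", "parent2"))
    stop("invalid value for 'recurrent'")
  invisible(cfg)
}

#' Save a configuration to YAML
#'
#' @param config A configuration list.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build a scenario grid from a configuration
#'
#' @param config A configuration list (see [load_config()]).
#' @return A `scenario_grid`.
#' @export
config_to_grid <- function(config) {
  validate_config(config)
  scenario_grid(
    dominance_ratios = config$dominance_ratios,
    heritabilities = config$heritabilities,
    systems = config$systems,
    generations = config$generations,
    replicates = config$replicates,
    n = config$population_size,
    map = build_map(config$group_count, config$markers_per_group,
                    config$spacing),
    random_mating_mode = config$random_mating_mode,
    recurrent = config$recurrent,
    qtl_positions_cM = config$qtl_positions_cM,
    master_seed = config$seed)
}

#' Export a genetic map as CSV
#'
#' Columns: `marker`, `group`, `position_cM`.
#'
#' @param map A `genetic_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  utils::write.csv(data.frame(marker = map$marker_ids, group = map$group,
                              position_cM = map$pos_cM),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export genotype dosages as CSV
#'
#' Individuals x markers matrix of 0/1/2 dosages with a leading
#' `individual_id` column.
#'
#' @param population A `population` (or dosage matrix).
#' @param map Optional `genetic_map` supplying marker column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_csv <- function(population, path, map = NULL) {
  d <- if (inherits(population, "population")) dosages(population)
       else as.matrix(population)
  colnames(d) <- if (!is.null(map)) map$marker_ids
                 else sprintf("M%04d", seq_len(ncol(d)))
  out <- data.frame(individual_id = seq_len(nrow(d)), d,
                    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV dosage matrix
#'
#' Inverse of [write_dosage_csv()]: expects an `individual_id` column
#' followed by one 0/1/2 column per marker.
#'
#' @param path CSV path.
#' @return Integer dosage matrix (individuals x markers).
#' @export
read_dosage_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- df$individual_id
  d <- as.matrix(df[setdiff(names(df), "individual_id")])
  storage.mode(d) <- "integer"
  rownames(d) <- ids
  d
}

#' Export phased genotypes as VCF
#'
#' Writes a minimal VCF 4.2 file with phased `GT` fields (allele 1 of the
#' simulation is the ALT allele). Positions encode the cM coordinate at
#' 0.0001 cM resolution; the linkage group is the contig.
#'
#' @param population A `population`.
#' @param map The `genetic_map`.
#' @param path Output path.
#' @param metadata Optional named character vector written as extra
#'   `##key=value` header lines (e.g. seed and configuration hash).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(population, map, path, metadata = NULL) {
  n <- pop_size(population)
  header <- c("##fileformat=VCFv4.2",
              "##source=multigen",
              sprintf("##contig=<ID=LG%02d>", seq_len(map$group_count)),
              if (!is.null(metadata))
                sprintf("##%s=%s", names(metadata), metadata),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sprintf("ind%04d", seq_len(n))),
                    collapse = "\t"))
  gt <- matrix(paste0(t(population$h1), "|", t(population$h2)),
               map$n_markers, n)
  body <- paste(sprintf("LG%02d", map$group),
                as.integer(round(map$pos_cM * 1e4)) + 1L,
                map$marker_ids, "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF into a dosage matrix
#'
#' Parses the `GT` field (phased or unphased) and counts ALT alleles.
#' Uses the vcfR package.
#'
#' @param path VCF path.
#' @return Integer dosage matrix (individuals x markers).
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- function(s) {
    vapply(strsplit(s, "[|/]"), function(a) sum(a == "1"), integer(1L))
  }
  d <- apply(gt, 1L, alt_count)                 # individuals x markers
  if (is.null(dim(d))) d <- matrix(d, nrow = 1L)
  storage.mode(d) <- "integer"
  colnames(d) <- rownames(gt)
  rownames(d) <- colnames(gt)
  d
}

#' Export phenotypes and true values as CSV
#'
#' Columns: `individual_id`, `generation`, `G`, `E`, `P`.
#'
#' @param phenotypes A `phenotype_set` (see [simulate_phenotypes()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes_csv <- function(phenotypes, path) {
  utils::write.csv(
    data.frame(individual_id = seq_along(phenotypes$P),
               generation = phenotypes$generation,
               G = phenotypes$G, E = phenotypes$E, P = phenotypes$P),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a trait architecture as CSV
#'
#' Columns: `qtl_marker`, `group`, `weight`, `additive_effect`,
#' `dominance_effect`.
#'
#' @param architecture A `trait_architecture`.
#' @param map The `genetic_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_architecture_csv <- function(architecture, map, path) {
  idx <- architecture$qtl_indices
  utils::write.csv(
    data.frame(qtl_marker = map$marker_ids[idx],
               group = map$group[idx],
               weight = architecture$weights,
               additive_effect = architecture$add_effects,
               dominance_effect = architecture$dom_effects),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export fitted marker effects as CSV
#'
#' Columns: `marker`, `training_freq`, `ma`, `md`.
#'
#' @param model A `marker_model`.
#' @param path Output path.
#' @param map Optional `genetic_map` for marker names.
#' @return `path`, invisibly.
#' @export
write_marker_model_csv <- function(model, path, map = NULL) {
  ids <- if (!is.null(map)) map$marker_ids
         else sprintf("M%04d", seq_along(model$ma))
  utils::write.csv(
    data.frame(marker = ids, training_freq = model$training_freqs,
               ma = model$ma, md = model$md),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Deterministic miniature data sets for tests and examples
#'
#' \describe{
#'   \item{`tiny_genome`}{1 linkage group x 5 markers at 10 cM, an F2 of
#'     20: map, population, architecture (1 QTL pair impossible, so a
#'     2-QTL architecture at the outer markers).}
#'   \item{`two_locus`}{a constructed 2-marker gamete pool with known
#'     haplotype counts for LD hand-checks.}
#'   \item{`toy_training`}{5 individuals x 3 markers with fixed dosages
#'     and phenotypes for ridge-solution oracles.}
#' }
#'
#' @param kind One of `"tiny_genome"`, `"two_locus"`, `"toy_training"`.
#' @param seed Seed for the stochastic fixtures.
#' @return A list; contents depend on `kind`.
#' @export
make_fixture <- function(kind = c("tiny_genome", "two_locus", "toy_training"),
                         seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "tiny_genome") {
    map <- build_map(1L, 5L, 10)
    set.seed(derive_seed(seed, "fixture", "tiny_genome"))
    founders <- make_founders(map)
    f2 <- make_f2(founders$parent1, founders$parent2, 20L, map)
    arch <- trait_architecture(map, dominance_ratio = 0.5,
                               qtl_indices = c(1L, 5L))
    list(map = map, f2 = f2, architecture = arch)
  } else if (kind == "two_locus") {
    # 40 gametes: 16 AB, 4 Ab, 4 aB, 16 ab -> D = 0.15, r2 = 0.36
    H <- rbind(matrix(c(1, 1), 16, 2, byrow = TRUE),
               matrix(c(1, 0), 4, 2, byrow = TRUE),
               matrix(c(0, 1), 4, 2, byrow = TRUE),
               matrix(c(0, 0), 16, 2, byrow = TRUE))
    storage.mode(H) <- "integer"
    list(haplotypes = H, D = 0.15, r2 = 0.36)
  } else {
    dos <- matrix(c(2, 1, 0,
                    1, 1, 2,
                    0, 2, 1,
                    2, 0, 0,
                    1, 2, 1), 5, 3, byrow = TRUE)
    storage.mode(dos) <- "integer"
    set.seed(derive_seed(seed, "fixture", "toy_training"))
    y <- c(1.8, 1.1, -0.4, 0.9, 0.6)
    list(dosages = dos, y = y)
  }
}
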