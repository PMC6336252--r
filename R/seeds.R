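#' Derive a reproducible child seed from a master seed
#'
#' Deterministically hashes a master seed together with an arbitrary set of
#' labels (replicate number, scenario tags, pipeline stage names) into an
#' integer seed below 2^31. A single master seed can thus fan out into
#' independent, stable streams: adding a new stage label does not perturb
#' the seeds of existing stages.
#'
#' @param master Master seed (single integer-valued number).
#' @param ... Additional labels: numbers or character strings.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(42, "replicate", 3, "meiosis")
#' @export
derive_seed <- function(master, ...) {
  if (length(master) != 1L || !is.finite(master) || master != round(master))
    stop("'master' must be a single integer-valued seed")
  parts <- list(master, ...)
  codes <- unlist(lapply(parts, function(p) {
    if (is.character(p)) utf8ToInt(paste(p, collapse = "|")) else as.numeric(p)
  }))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- 17
  for (v in codes) {
    # multiplier small enough that h * 69069 + v stays exact in doubles
    h <- (h * 69069 + (v %% m) + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}
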