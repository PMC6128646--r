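#' Configuration for a simulated pooled growth competition
#'
#' Describes a pooled deletion-library culture grown for \code{doublings}
#' pool doublings in parallel control and treatment conditions. Each mutant
#' i carries a relative growth rate \code{rho[i]} under treatment, expressed
#' as the fraction of pool doublings it achieves: \code{rho = 1} is neutral,
#' \code{rho = 0} does not divide at all, so the downstream growth
#' inhibition score approaches \code{1 - rho} for rare mutants.
#'
#' @param n_mutants Number of mutants in the pool.
#' @param initial_abundances Positive relative abundances at inoculation;
#'   normalized to sum to 1. Default: uniform.
#' @param rho Relative growth rates under treatment, in \code{[0, 1]}, one
#'   per mutant. Default: all 1 (no effect).
#' @param doublings Number of pool doublings g before harvest; the screens
#'   this models use 5.
#' @param rho_jitter_sd Standard deviation of optional lognormal
#'   replicate-to-replicate jitter applied to \code{rho} by
#'   [simulateScreenCounts()] (not by [simulatePool()], which is
#'   noise-free). Default 0.02.
#' @param seed Integer seed consumed by the stochastic generators.
#'
#' @return A list of class \code{PoolSimConfig}.
#' @seealso [simulatePool()], [simulateScreenCounts()]
#' @export
poolSimConfig <- function(n_mutants, initial_abundances = NULL, rho = NULL,
                          doublings = 5, rho_jitter_sd = 0.02, seed = NULL) {
  assertScalarNumber(n_mutants, "n_mutants", lower = 1)
  assertScalarNumber(doublings, "doublings", lower = 0, strict_lower = TRUE)
  assertScalarNumber(rho_jitter_sd, "rho_jitter_sd", lower = 0)
  n_mutants <- as.integer(n_mutants)
  if (is.null(initial_abundances))
    initial_abundances <- rep(1 / n_mutants, n_mutants)
  if (length(initial_abundances) != n_mutants ||
      any(!is.finite(initial_abundances)) || any(initial_abundances <= 0))
    stop("'initial_abundances' must be ", n_mutants, " finite positive values")
  initial_abundances <- initial_abundances / sum(initial_abundances)
  if (is.null(rho))
    rho <- rep(1, n_mutants)
  if (length(rho) != n_mutants || any(!is.finite(rho)) ||
      any(rho < 0) || any(rho > 1))
    stop("'rho' must be ", n_mutants, " values in [0, 1]")
  structure(list(n_mutants = n_mutants,
                 initial_abundances = initial_abundances,
                 rho = rho, doublings = doublings,
                 rho_jitter_sd = rho_jitter_sd, seed = seed),
            class = "PoolSimConfig")
}

#' Noise-free pooled exponential growth
#'
#' Propagates the initial pool composition through g pool doublings:
#' control abundance of mutant i is proportional to \code{a0_i * 2^g},
#' treatment abundance to \code{a0_i * 2^(g * rho_i)}; both vectors are
#' renormalized to sum to 1. The operation is deterministic; sampling noise
#' enters only when reads or counts are drawn from these abundances.
#'
#' @param config A [poolSimConfig()].
#' @param rho Optional override of the growth rates in \code{config}
#'   (used internally for replicate jitter).
#' @return List with numeric vectors \code{control} and \code{treatment}
#'   (each summing to 1) and the \code{rho} used.
#'
#' @examples
#' cfg <- poolSimConfig(4, rho = c(1, 1, 1, 0))
#' simulatePool(cfg)$treatment
#' @export
simulatePool <- function(config, rho = config$rho) {
  stopifnot(inherits(config, "PoolSimConfig"))
  if (length(rho) != config$n_mutants || any(!is.finite(rho)) || any(rho < 0))
    stop("'rho' must be non-negative and finite for every mutant")
  g <- config$doublings
  a0 <- config$initial_abundances
  control <- a0 * 2^g
  treatment <- a0 * 2^(g * rho)
  if (any(!is.finite(control)) || any(!is.finite(treatment)))
    stop("non-finite abundances; reduce doublings or abundances")
  list(control = control / sum(control),
       treatment = treatment / sum(treatment),
       rho = rho)
}

#' Simulate a random barcode library
#'
#' Draws \code{n_mutants} distinct random barcodes of fixed length,
#' rejection-sampling until all are unique.
#'
#' @param n_mutants Number of mutants.
#' @param barcode_length Barcode length in nt (default 20).
#' @param seed Integer seed.
#' @return A [BarcodeLibrary-class].
#' @export
simulateBarcodeLibrary <- function(n_mutants, barcode_length = 20,
                                   seed = NULL) {
  withSeed(seed, {
    draw <- function(n) {
      m <- matrix(sample(c("A", "C", "G", "T"), n * barcode_length,
                         replace = TRUE), nrow = n)
      apply(m, 1, paste0, collapse = "")
    }
    bc <- unique(draw(n_mutants))
    while (length(bc) < n_mutants)
      bc <- unique(c(bc, draw(n_mutants - length(bc))))
    ids <- sprintf("mut%04d", seq_len(n_mutants))
    barcodeLibrary(bc[seq_len(n_mutants)], mutant_ids = ids,
                   genes = sprintf("gene%04d", seq_len(n_mutants)))
  })
}

#' Simulate per-screen barcode count tables
#'
#' Runs the noise-free pool model, optionally jitters the relative growth
#' rates per screen (lognormal, sd \code{config$rho_jitter_sd}, emulating
#' biological replicate variability; jittered rates may slightly exceed 1),
#' then draws multinomial read counts at the requested depth for the
#' control and treatment samples of each screen.
#'
#' @param config A [poolSimConfig()].
#' @param depth Total assigned reads per sample.
#' @param n_screens Number of independent screens (the study performed 2).
#' @param seed Integer seed; overrides \code{config$seed} when given.
#' @param mutant_ids Optional mutant identifiers (default
#'   \code{mut0001...}).
#' @return List of length \code{n_screens}; each element has
#'   \code{CountTable}s \code{control} and \code{treatment} plus the
#'   effective (jittered) \code{rho}.
#' @export
simulateScreenCounts <- function(config, depth, n_screens = 2,
                                 seed = config$seed, mutant_ids = NULL) {
  stopifnot(inherits(config, "PoolSimConfig"))
  assertScalarNumber(depth, "depth", lower = 1)
  if (is.null(mutant_ids))
    mutant_ids <- sprintf("mut%04d", seq_len(config$n_mutants))
  withSeed(seed, {
    lapply(seq_len(n_screens), function(s) {
      rho_s <- config$rho
      if (config$rho_jitter_sd > 0)
        rho_s <- rho_s * exp(stats::rnorm(length(rho_s),
                                          sd = config$rho_jitter_sd))
      ab <- simulatePool(config, rho = rho_s)
      mk <- function(p, cond) {
        cnt <- as.integer(stats::rmultinom(1, size = depth, prob = p))
        methods::new("CountTable",
          counts = stats::setNames(cnt, mutant_ids),
          genes = mutant_ids,
          sample_id = sprintf("screen%d_%s", s, cond),
          condition = cond, unassigned = 0L,
          total_reads = as.integer(depth))
      }
      list(control = mk(ab$control, "control"),
           treatment = mk(ab$treatment, "treatment"),
           rho = rho_s)
    })
  })
}
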