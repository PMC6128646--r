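#' Pseudocounted relative abundances
#'
#' Converts raw barcode counts to relative frequencies after adding a
#' pseudocount to every mutant:
#' \code{freq_i = (count_i + pc) / sum_j (count_j + pc)}. The pseudocount
#' keeps frequencies finite for mutants that dropped to zero reads under
#' treatment (the strongest hits do exactly that).
#'
#' @param counts Numeric vector of non-negative counts, or a
#'   [CountTable-class].
#' @param pseudocount Non-negative value added to every count
#'   (default 0.5).
#' @return Named numeric vector of frequencies summing to 1.
#'
#' @examples
#' relativeAbundance(c(a = 10, b = 10, c = 20), pseudocount = 0)
#' @export
relativeAbundance <- function(counts, pseudocount = 0.5) {
  if (methods::is(counts, "CountTable"))
    counts <- mutantCounts(counts)
  assertScalarNumber(pseudocount, "pseudocount", lower = 0)
  if (length(counts) == 0 || anyNA(counts) || any(counts < 0))
    stop("'counts' must be non-negative and non-missing")
  if (sum(counts) == 0 && pseudocount == 0)
    stop("all-zero count table: set a positive pseudocount")
  x <- counts + pseudocount
  if (sum(x) == 0)
    stop("all-zero count table")
  x / sum(x)
}

#' Growth inhibition (GI) scores
#'
#' The GI score of mutant i is the normalized log2 ratio of its control
#' and treatment frequencies, divided by the number of pool doublings g:
#' \deqn{GI_i = \log_2(f^{ctrl}_i / f^{trt}_i) / g.}
#' A mutant unaffected by the treatment scores 0; a mutant that does not
#' divide at all is depleted by the full g doublings and scores about 1.
#' Dividing by the frequency ratio (rather than raw counts) normalizes for
#' constitutively slow-growing mutants.
#'
#' @param control_freq,treatment_freq Matched frequency vectors (e.g. from
#'   [relativeAbundance()]).
#' @param doublings Pool doublings g between inoculation and harvest; the
#'   screens this models use 5.
#' @return Numeric vector of GI scores, named like the inputs.
#'
#' @examples
#' giScores(c(0.001, 0.5), c(0.000125, 0.5), doublings = 5)
#' @export
giScores <- function(control_freq, treatment_freq, doublings = 5) {
  assertScalarNumber(doublings, "doublings", lower = 0, strict_lower = TRUE)
  if (length(control_freq) != length(treatment_freq))
    stop("control and treatment frequency vectors must be matched")
  if (any(treatment_freq == 0, na.rm = TRUE) ||
      any(control_freq == 0, na.rm = TRUE))
    stop("zero frequencies: recompute abundances with a positive pseudocount")
  log2(control_freq / treatment_freq) / doublings
}

#' Robust Z-scores in normalized-IQR units
#'
#' Standardizes GI scores as the deviation from the median in units of the
#' normalized interquartile range,
#' \code{NIQR = IQR / (qnorm(.75) - qnorm(.25)) = IQR / 1.349},
#' so the NIQR estimates the standard deviation under normality and the
#' bulk of (null) mutants behaves like N(0, 1).
#'
#' @param gi Numeric vector of GI scores; \code{NA}s are propagated.
#' @param quantile_type Quantile algorithm passed to
#'   \code{stats::quantile} (default 7, linear interpolation).
#' @return Numeric vector of robust Z-scores.
#'
#' @examples
#' robustZ(c(1, 2, 3, 4, 5))   # z of 5 is 1.349
#' @export
robustZ <- function(gi, quantile_type = 7) {
  x <- gi[is.finite(gi)]
  if (length(x) < 4)
    stop("need at least 4 finite GI scores")
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = quantile_type,
                        names = FALSE)
  iqr <- qs[3] - qs[1]
  if (iqr <= 0)
    stop("degenerate screen: IQR of GI scores is 0")
  niqr <- iqr / (stats::qnorm(0.75) - stats::qnorm(0.25))
  (gi - qs[2]) / niqr
}

#' Tail-area false discovery rates for robust Z-scores
#'
#' Converts robust Z-scores to one-sided p-values under the standard
#' normal null implied by the NIQR standardization
#' (\code{p_i = 1 - pnorm(z_i)}; sensitivity is the upper tail), then
#' attaches the Benjamini-Hochberg step-up envelope
#' \deqn{q_i = \min_{j : p_j \ge p_i} \pi_0 M p_j / rank_j,}
#' clipped to \code{[0, 1]}. With \code{pi0 = 1} this is the conservative
#' tail-area FDR.
#'
#' @param z Numeric vector of robust Z-scores (finite).
#' @param pi0 Null proportion: a number in \code{(0, 1]} or \code{"auto"}
#'   for the Storey estimate at lambda = 0.5,
#'   \code{min(1, mean(p > 0.5) / 0.5)}.
#' @return Numeric vector of q-values, monotone non-decreasing in p.
#'
#' @examples
#' z <- c(4, rnorm(99))
#' tailFDR(z)[1]
#' @export
tailFDR <- function(z, pi0 = 1) {
  if (length(z) == 0)
    stop("empty z vector")
  if (any(!is.finite(z)))
    stop("z scores must be finite")
  p <- stats::pnorm(z, lower.tail = FALSE)
  M <- length(p)
  if (identical(pi0, "auto")) {
    pi0 <- min(1, mean(p > 0.5) / 0.5)
    if (pi0 <= 0) pi0 <- 1 / M  # degenerate: everything in the tail
  }
  assertScalarNumber(pi0, "pi0", lower = 0, upper = 1, strict_lower = TRUE)
  o <- order(p)
  q <- pi0 * M * p[o] / seq_len(M)
  q <- rev(cummin(rev(q)))
  q <- pmin(1, q)
  out <- numeric(M)
  out[o] <- q
  out
}

#' Call toxin-sensitive mutants across screens
#'
#' Applies the FDR cutoff per screen and labels each mutant
#' \code{sensitive_both} (passes in every screen with data, at least two
#' screens), \code{sensitive_one} (passes in at least one screen but not
#' all, or is covered by a single screen), or \code{not_sensitive}.
#'
#' @param q Numeric matrix of q-values, mutants in rows, screens in
#'   columns; \code{NA} marks mutants absent from a screen's library
#'   version.
#' @param cutoff FDR cutoff (default 0.1).
#' @param rule \code{"both"} (default): the top label
#'   \code{sensitive_both} requires passing in every screen with data;
#'   \code{"any"}: one passing screen suffices (the label then reflects
#'   how many screens actually passed).
#' @return A \link[S4Vectors]{DataFrame} with per-mutant \code{n_screens}
#'   (screens with data), \code{n_pass}, \code{call}, and
#'   \code{sensitive} (logical, under the requested rule).
#'
#' @examples
#' q <- rbind(a = c(0.05, 0.08), b = c(0.05, 0.5), c = c(0.5, 0.9))
#' callSensitive(q)$call
#' @export
callSensitive <- function(q, cutoff = 0.1, rule = c("both", "any")) {
  q <- as.matrix(q)
  rule <- match.arg(rule)
  assertScalarNumber(cutoff, "cutoff", lower = 0, upper = 1)
  n_data <- rowSums(!is.na(q))
  if (any(n_data == 0))
    stop("every mutant needs data in at least one screen")
  n_pass <- rowSums(q <= cutoff, na.rm = TRUE)
  call <- ifelse(n_pass == n_data & n_data >= 2, "sensitive_both",
          ifelse(n_pass >= 1, "sensitive_one", "not_sensitive"))
  sensitive <- if (rule == "both") call == "sensitive_both" else n_pass >= 1
  S4Vectors::DataFrame(n_screens = unname(n_data), n_pass = unname(n_pass),
                       call = unname(call), sensitive = unname(sensitive),
                       row.names = rownames(q))
}

#' Expressivity categories for called mutants
#'
#' Assigns ordinal sensitivity strength (\code{high}/\code{medium}/
#' \code{low}) to called mutants from their GI scores. By default the cut
#' points are the tertiles of the mean GI among called mutants; explicit
#' cut points can be supplied. Mutants without a sensitivity call get
#' \code{NA}: the categories are advisory and not comparable across
#' scoring methods.
#'
#' @param calls Character vector of calls as produced by
#'   [callSensitive()] (\code{"sensitive_both"}, \code{"sensitive_one"},
#'   \code{"not_sensitive"}).
#' @param gi Numeric vector of GI scores (e.g. per-mutant mean across
#'   screens), parallel to \code{calls}.
#' @param thresholds \code{NULL} for tertiles among called mutants, or an
#'   ascending pair \code{c(low_cut, high_cut)}: GI > high_cut is
#'   \code{high}, GI > low_cut is \code{medium}, the rest \code{low}.
#' @return Character vector of labels, \code{NA} for uncalled mutants.
#' @export
classifyExpressivity <- function(calls, gi, thresholds = NULL) {
  stopifnot(length(calls) == length(gi))
  called <- calls %in% c("sensitive_both", "sensitive_one")
  if (is.null(thresholds)) {
    if (sum(called) == 0)
      return(rep(NA_character_, length(calls)))
    thresholds <- stats::quantile(gi[called], c(1, 2) / 3, na.rm = TRUE,
                                  names = FALSE)
  }
  if (length(thresholds) != 2 || is.unsorted(thresholds))
    stop("'thresholds' must be an ascending pair of GI cut points")
  lab <- ifelse(gi > thresholds[2], "high",
         ifelse(gi > thresholds[1], "medium", "low"))
  lab[!called] <- NA_character_
  lab
}

#' Score one screen from its control/treatment count tables
#'
#' Convenience wrapper: pseudocounted frequencies, GI scores and robust
#' Z-scores with q-values for a single screen.
#'
#' @param control,treatment [CountTable-class] objects (or named count
#'   vectors) for the paired samples.
#' @param doublings Pool doublings g (default 5).
#' @param pseudocount Added to every count before frequencies
#'   (default 0.5).
#' @param pi0 Null proportion for [tailFDR()].
#' @return A \link[S4Vectors]{DataFrame} with \code{mutant}, \code{gene}
#'   (when available), \code{control_freq}, \code{treatment_freq},
#'   \code{gi}, \code{z}, \code{q}.
#'
#' @examples
#' cfg <- poolSimConfig(100, rho = c(rep(1, 95), rep(0.4, 5)),
#'                      rho_jitter_sd = 0)
#' scr <- simulateScreenCounts(cfg, depth = 1e5, n_screens = 1, seed = 3)
#' head(scoreScreen(scr[[1]]$control, scr[[1]]$treatment))
#' @export
scoreScreen <- function(control, treatment, doublings = 5,
                        pseudocount = 0.5, pi0 = 1) {
  gene <- if (methods::is(control, "CountTable")) control@genes else NULL
  cf <- relativeAbundance(control, pseudocount)
  tf <- relativeAbundance(treatment, pseudocount)
  if (!is.null(names(cf)) && !is.null(names(tf))) {
    stopifnot(identical(names(cf), names(tf)))
  }
  gi <- giScores(cf, tf, doublings)
  z <- robustZ(gi)
  q <- tailFDR(z, pi0 = pi0)
  out <- S4Vectors::DataFrame(mutant = names(cf) %||% seq_along(cf),
    control_freq = unname(cf), treatment_freq = unname(tf),
    gi = unname(gi), z = unname(z), q = q)
  if (!is.null(gene)) out$gene <- gene
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
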