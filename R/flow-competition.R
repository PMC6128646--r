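#' Gate configuration for the competitive growth assay
#'
#' Thresholds for the three hard gates plus the GFP classification bands.
#' Intensities are linear arbitrary units. Defaults are calibrated to the
#' synthetic event generator ([simulateFlowEvents()]) and to the
#' convention that FITC intensities between 1e2 and 1e3 are an ambiguous
#' GFP+/GFP- band that is excluded from classification.
#'
#' @param dapi_max Maximum 450/50 (DAPI) intensity for a live cell; events
#'   above are DAPI-permeable (dead) and removed.
#' @param fsc_range,ssc_range Two-element vectors: the FSC-A and SSC box
#'   retaining intact single cells and excluding debris.
#' @param doublet_band Allowed FSC-A/FSC-H ratio interval for singlets;
#'   doublets pulse roughly twice the area per height.
#' @param gfp_ambiguous FITC interval excluded from GFP classification
#'   (default \code{c(1e2, 1e3)}).
#' @param gfp_positive_min Minimum FITC intensity of a GFP+ cell; must not
#'   undercut the upper edge of the ambiguous band.
#' @return A list of class \code{GateConfig}.
#' @export
gateConfig <- function(dapi_max = 316,
                       fsc_range = c(150, 2500),
                       ssc_range = c(30, 800),
                       doublet_band = c(0.8, 1.4),
                       gfp_ambiguous = c(1e2, 1e3),
                       gfp_positive_min = 1e3) {
  ordered2 <- function(x, nm) {
    if (length(x) != 2 || any(!is.finite(x)) || x[1] >= x[2])
      stop("'", nm, "' must be an ordered pair")
    x
  }
  assertScalarNumber(dapi_max, "dapi_max", lower = 0)
  fsc_range <- ordered2(fsc_range, "fsc_range")
  ssc_range <- ordered2(ssc_range, "ssc_range")
  doublet_band <- ordered2(doublet_band, "doublet_band")
  gfp_ambiguous <- ordered2(gfp_ambiguous, "gfp_ambiguous")
  assertScalarNumber(gfp_positive_min, "gfp_positive_min", lower = 0)
  if (gfp_positive_min < gfp_ambiguous[2])
    stop("'gfp_positive_min' must not undercut the ambiguous band")
  structure(list(dapi_max = dapi_max, fsc_range = fsc_range,
                 ssc_range = ssc_range, doublet_band = doublet_band,
                 gfp_ambiguous = gfp_ambiguous,
                 gfp_positive_min = gfp_positive_min),
            class = "GateConfig")
}

flowColumns <- c("FSC_A", "FSC_H", "SSC", "DAPI", "FITC", "PE")

checkFlowEvents <- function(events) {
  if (!is.data.frame(events) || !all(flowColumns %in% names(events)))
    stop("flow event table needs columns ",
         paste(flowColumns, collapse = ", "))
  num <- events[flowColumns]
  if (any(!vapply(num, is.numeric, logical(1))) ||
      any(vapply(num, function(v) any(!is.finite(v) | v < 0), logical(1))))
    stop("intensities must be complete, finite and >= 0")
  invisible(events)
}

#' Apply the hard gating cascade
#'
#' Three hard gates with intersection semantics (so gate order cannot
#' change the retained set): (1) viability, DAPI <= \code{dapi_max};
#' (2) intact-cell scatter box on FSC-A and SSC; (3) doublet
#' discrimination, FSC-A/FSC-H ratio within \code{doublet_band}. The
#' attrition report counts, per gate, events removed in the configured
#' sequence.
#'
#' @param events Data frame with columns FSC_A, FSC_H, SSC, DAPI, FITC, PE
#'   (e.g. from [simulateFlowEvents()] or [readFlowCSV()]).
#' @param config A [gateConfig()].
#' @return List with \code{events} (retained rows) and \code{attrition}, a
#'   data frame with per-gate \code{before}, \code{after}, \code{removed}
#'   and \code{fraction_removed} plus a \code{total} row (fraction of all
#'   input events removed).
#' @export
applyGates <- function(events, config = gateConfig()) {
  stopifnot(inherits(config, "GateConfig"))
  checkFlowEvents(events)
  live <- events$DAPI <= config$dapi_max
  box <- events$FSC_A >= config$fsc_range[1] &
         events$FSC_A <= config$fsc_range[2] &
         events$SSC >= config$ssc_range[1] &
         events$SSC <= config$ssc_range[2]
  ratio <- ifelse(events$FSC_H > 0, events$FSC_A / events$FSC_H, Inf)
  singlet <- ratio >= config$doublet_band[1] & ratio <= config$doublet_band[2]

  keep <- live & box & singlet
  n0 <- nrow(events)
  seq_keep <- list(viability = live,
                   scatter_box = live & box,
                   doublet = keep)
  before <- c(n0, sum(seq_keep$viability), sum(seq_keep$scatter_box))
  after <- vapply(seq_keep, sum, integer(1))
  att <- data.frame(gate = c(names(seq_keep), "total"),
    before = c(before, n0), after = c(after, sum(keep)),
    removed = c(before - after, n0 - sum(keep)))
  att$fraction_removed <- ifelse(att$before > 0,
                                 att$removed / att$before, 0)
  if (sum(keep) == 0)
    stop("all events removed by gating: uninterpretable sample")
  list(events = events[keep, , drop = FALSE], attrition = att)
}

#' Classify gated events as GFP+ / GFP-
#'
#' FITC above \code{gfp_positive_min} is GFP+; FITC below the ambiguous
#' band is GFP-; events inside the ambiguous band (default 1e2-1e3
#' arbitrary units) are excluded as unresolvable GFP+/GFP-.
#'
#' @param events Gated event table.
#' @param config A [gateConfig()].
#' @return Named list of counts: \code{gfp_pos}, \code{gfp_neg},
#'   \code{ambiguous_excluded}.
#'
#' @examples
#' ev <- data.frame(FSC_A = 300, FSC_H = 300, SSC = 100, DAPI = 10,
#'                  FITC = c(1e4, 50, 5e2), PE = 30)
#' classifyGFP(ev)
#' @export
classifyGFP <- function(events, config = gateConfig()) {
  stopifnot(inherits(config, "GateConfig"))
  checkFlowEvents(events)
  fitc <- events$FITC
  pos <- fitc > config$gfp_positive_min
  amb <- fitc >= config$gfp_ambiguous[1] & fitc <= config$gfp_ambiguous[2] &
         !pos
  neg <- !pos & !amb & fitc < config$gfp_ambiguous[1]
  # anything between the ambiguous band and the GFP+ threshold is also
  # unresolved (empty interval under the defaults)
  other <- !pos & !amb & !neg
  list(gfp_pos = sum(pos), gfp_neg = sum(neg),
       ambiguous_excluded = sum(amb) + sum(other))
}

#' Normalized competitive growth ratio
#'
#' From GFP+/GFP- counts of the four competition samples, computes the
#' mutant fraction without/with toxicant
#' \code{W_m = M-GFP- / (M-GFP- + WT-GFP+)} (and \code{W_m*}), the
#' reference fraction \code{W_r = WT-GFP- / (WT-GFP- + WT-GFP+)} (and
#' \code{W_r*}) which captures the small rate of GFP+ cells scored GFP-,
#' the corrected ratios \code{W_n = W_m / W_r}, \code{W_n* = W_m* / W_r*},
#' and the growth ratio \code{W_n* / W_n}. The raw mutant/wild-type count
#' ratio \code{W_N = W_M / W_R} is compared against the assay detection
#' floor; results below the floor are flagged, never clamped.
#'
#' @param mutant_untreated,mutant_treated,ref_untreated,ref_treated Count
#'   lists as returned by [classifyGFP()] (elements \code{gfp_pos},
#'   \code{gfp_neg}), for the mutant and reference competitions with and
#'   without toxicant.
#' @param detection_floor Lowest trustworthy treated \code{W_M/W_R}
#'   (default 0.03).
#' @return A [CompetitionResult-class].
#'
#' @examples
#' s <- function(p, n) list(gfp_pos = p, gfp_neg = n)
#' growthRatio(s(5000, 5000), s(9000, 1000), s(5000, 5000), s(5000, 5000))
#' @export
growthRatio <- function(mutant_untreated, mutant_treated,
                        ref_untreated, ref_treated,
                        detection_floor = 0.03) {
  get2 <- function(x, nm) {
    if (!all(c("gfp_pos", "gfp_neg") %in% names(x)))
      stop("'", nm, "' needs elements gfp_pos and gfp_neg")
    c(pos = as.numeric(x$gfp_pos), neg = as.numeric(x$gfp_neg))
  }
  mu <- get2(mutant_untreated, "mutant_untreated")
  mt <- get2(mutant_treated, "mutant_treated")
  ru <- get2(ref_untreated, "ref_untreated")
  rt <- get2(ref_treated, "ref_treated")
  if (any(c(mu["pos"], mt["pos"], ru["pos"], rt["pos"]) == 0))
    stop("zero GFP+ count: normalization undefined")
  frac <- function(v) unname(v["neg"] / (v["neg"] + v["pos"]))
  w_m <- frac(mu); w_m_star <- frac(mt)
  w_r <- frac(ru); w_r_star <- frac(rt)
  if (w_r == 0 || w_r_star == 0)
    stop("reference GFP- count is zero: cannot correct for GFP loss")
  w_n <- w_m / w_r
  w_n_star <- w_m_star / w_r_star
  w_big_n <- c(untreated = unname(mu["neg"] / mu["pos"]),
               treated = unname(mt["neg"] / mt["pos"]))
  methods::new("CompetitionResult",
    w_m = w_m, w_r = w_r, w_m_star = w_m_star, w_r_star = w_r_star,
    w_n = w_n, w_n_star = w_n_star,
    growth_ratio = w_n_star / w_n,
    w_big_n = w_big_n,
    below_detection = unname(w_big_n["treated"] < detection_floor))
}

#' @rdname CompetitionResult-class
#' @param object A \code{CompetitionResult}.
#' @export
setMethod("show", "CompetitionResult", function(object) {
  cat(sprintf(
    "CompetitionResult: growth ratio %.4f\n  W_m %.4f  W_m* %.4f  W_r %.4f  W_r* %.4f\n  W_n %.4f  W_n* %.4f  W_M/W_R (treated) %.4f%s\n",
    object@growth_ratio, object@w_m, object@w_m_star, object@w_r,
    object@w_r_star, object@w_n, object@w_n_star,
    object@w_big_n["treated"],
    if (object@below_detection) "  [below detection floor]" else ""))
})

#' Two-tailed Student's t-test on replicate growth ratios
#'
#' Pooled-variance two-sample Student's t-test (the form implied by
#' "Student's t-test" with equal replicate numbers); Welch's form is
#' available by flag. Degenerate inputs with zero variance in both groups
#' return t = 0, p = 1 when the means are equal.
#'
#' @param a,b Numeric vectors of replicate growth ratios (>= 2 each; the
#'   assay uses 3).
#' @param welch Use Welch's unequal-variance form instead.
#' @return List with \code{t}, \code{df}, \code{p}.
#'
#' @examples
#' replicateTest(c(0.9, 1.0, 1.1), c(0.4, 0.5, 0.6))
#' @export
replicateTest <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 replicates per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Read or write flow event tables as CSV
#'
#' Plain CSV with header \code{FSC_A,FSC_H,SSC,DAPI,FITC,PE}, one row per
#' event; extra columns (e.g. simulation truth labels) are preserved.
#'
#' @param path File path.
#' @param events Event data frame (for writing).
#' @return \code{readFlowCSV} returns the validated data frame;
#'   \code{writeFlowCSV} returns \code{path} invisibly.
#' @export
readFlowCSV <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  checkFlowEvents(ev)
  ev
}

#' @rdname readFlowCSV
#' @export
writeFlowCSV <- function(events, path) {
  checkFlowEvents(events)
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
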