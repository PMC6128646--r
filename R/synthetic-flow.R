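#' Configuration for simulated flow-cytometry events
#'
#' Describes a stained competition sample as a mixture of event classes:
#' live singlet GFP+ wild type, live singlet GFP- competitor,
#' DAPI-permeable dead cells, doublets (FSC-A about twice FSC-H) and
#' non-cellular debris. Intensities are simulated on the log10 scale with
#' normal clusters and reported in linear arbitrary units, matching the
#' 1e2-1e3 FITC ambiguity-band convention.
#'
#' @param n_events Number of events to draw.
#' @param fractions Named numeric vector or list with entries
#'   \code{gfp_pos}, \code{gfp_neg}, \code{dead}, \code{doublet},
#'   \code{debris}; each in \code{[0, 1]}, sum at most 1 (the vector is
#'   renormalized to 1, preserving proportions).
#' @param fitc_cluster_params List with \code{pos} and \code{neg}, each
#'   \code{c(mean, sd)} of the log10 FITC intensity. Cluster medians must
#'   be separated by at least 1 log10 unit.
#' @param gfp_loss_rate Fraction of truly GFP+ cells whose FITC signal
#'   falls in the GFP- cluster (observed range about 0.001-0.01; default
#'   0.005).
#' @param seed Integer seed.
#' @return A list of class \code{FlowSimConfig}.
#' @export
flowSimConfig <- function(n_events,
                          fractions = c(gfp_pos = 0.475, gfp_neg = 0.475,
                                        dead = 0.01, doublet = 0.02,
                                        debris = 0.02),
                          fitc_cluster_params = list(pos = c(4.0, 0.25),
                                                     neg = c(1.2, 0.30)),
                          gfp_loss_rate = 0.005, seed = NULL) {
  assertScalarNumber(n_events, "n_events", lower = 1)
  fr <- unlist(fractions)
  need <- c("gfp_pos", "gfp_neg", "dead", "doublet", "debris")
  if (!all(need %in% names(fr)))
    stop("'fractions' needs entries ", paste(need, collapse = ", "))
  fr <- fr[need]
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1) || sum(fr) > 1 + 1e-9)
    stop("'fractions' must lie in [0, 1] with sum <= 1")
  if (sum(fr) <= 0)
    stop("'fractions' must have positive sum")
  fr <- fr / sum(fr)
  p <- fitc_cluster_params
  if (!all(c("pos", "neg") %in% names(p)) ||
      length(p$pos) != 2 || length(p$neg) != 2)
    stop("'fitc_cluster_params' needs pos = c(mean, sd), neg = c(mean, sd)")
  if (abs(p$pos[1] - p$neg[1]) < 1)
    stop("GFP+ and GFP- FITC cluster medians must be separated by >= 1 ",
         "log10 unit")
  assertScalarNumber(gfp_loss_rate, "gfp_loss_rate", lower = 0, upper = 1)
  structure(list(n_events = as.integer(n_events), fractions = fr,
                 fitc_cluster_params = p, gfp_loss_rate = gfp_loss_rate,
                 seed = seed),
            class = "FlowSimConfig")
}

rlog10norm <- function(n, mean, sd) 10^stats::rnorm(n, mean, sd)

#' Simulate flow-cytometry events for a competition sample
#'
#' Draws per-event intensities from the mixture declared by the config.
#' Live singlets have FSC-A approximately equal to FSC-H; doublets have
#' FSC-A about 2x FSC-H; dead cells carry high 450/50 (DAPI) intensity;
#' debris scatters low. A fraction \code{gfp_loss_rate} of truly GFP+
#' cells emits FITC from the GFP- cluster. Truth labels are retained so
#' gating and classification can be scored against them.
#'
#' @param config A [flowSimConfig()].
#' @return Data frame with columns \code{FSC_A, FSC_H, SSC, DAPI, FITC,
#'   PE} plus truth columns \code{label} (event class) and
#'   \code{gfp_lost}.
#'
#' @examples
#' ev <- simulateFlowEvents(flowSimConfig(1000, seed = 1))
#' table(ev$label)
#' @export
simulateFlowEvents <- function(config) {
  stopifnot(inherits(config, "FlowSimConfig"))
  withSeed(config$seed, {
    n <- config$n_events
    cls <- sample(names(config$fractions), n, replace = TRUE,
                  prob = config$fractions)
    fp <- config$fitc_cluster_params
    fsc_h <- rlog10norm(n, 2.7, 0.08)
    ratio <- stats::rnorm(n, 1.0, 0.05)
    ssc <- rlog10norm(n, 2.2, 0.15)
    dapi <- rlog10norm(n, 1.5, 0.2)
    fitc <- rlog10norm(n, fp$neg[1], fp$neg[2])
    pe <- rlog10norm(n, 1.5, 0.3)
    gfp_lost <- rep(FALSE, n)

    ip <- cls == "gfp_pos"
    if (any(ip)) {
      lost <- ip & stats::runif(n) < config$gfp_loss_rate
      gfp_lost <- lost
      fitc[ip & !lost] <- rlog10norm(sum(ip & !lost), fp$pos[1], fp$pos[2])
      pe[ip] <- rlog10norm(sum(ip), 1.8, 0.25)
    }
    idead <- cls == "dead"
    dapi[idead] <- rlog10norm(sum(idead), 3.2, 0.2)
    idbl <- cls == "doublet"
    if (any(idbl)) {
      ratio[idbl] <- stats::rnorm(sum(idbl), 2.0, 0.1)
      ssc[idbl] <- rlog10norm(sum(idbl), 2.4, 0.12)
      pos_half <- idbl & stats::runif(n) < 0.5
      fitc[pos_half] <- rlog10norm(sum(pos_half), fp$pos[1], fp$pos[2])
    }
    idbr <- cls == "debris"
    if (any(idbr)) {
      nd <- sum(idbr)
      fsc_h[idbr] <- rlog10norm(nd, 1.5, 0.3)
      ratio[idbr] <- stats::rnorm(nd, 1.0, 0.2)
      ssc[idbr] <- rlog10norm(nd, 1.2, 0.3)
      fitc[idbr] <- rlog10norm(nd, 0.8, 0.3)
      dapi[idbr] <- rlog10norm(nd, 1.3, 0.3)
    }
    data.frame(FSC_A = pmax(0, fsc_h * ratio), FSC_H = fsc_h, SSC = ssc,
               DAPI = dapi, FITC = fitc, PE = pe,
               label = cls, gfp_lost = gfp_lost)
  })
}

#' Simulate a full four-sample growth competition
#'
#' Models the competitive growth assay: mutant (GFP-) and wild-type
#' (GFP+) cells mixed 1:1, grown for \code{generations} pool doublings
#' with or without toxicant, alongside a reference competition of
#' untagged wild type (GFP-) versus tagged wild type (GFP+). The mutant
#' achieves a fraction \code{rho} of the wild-type doublings under each
#' condition. Event tables are then drawn with [simulateFlowEvents()].
#'
#' @param rho_treated Mutant relative growth rate with toxicant.
#' @param rho_untreated Mutant relative growth rate without toxicant
#'   (default 1, neutral).
#' @param generations Wild-type doublings during the competition (the
#'   assay grows cultures about 7 generations).
#' @param n_events Events per sample.
#' @param gfp_loss_rate,background_fractions Passed to the event
#'   generator: \code{background_fractions} is a named vector with
#'   \code{dead}, \code{doublet}, \code{debris} (live singlets fill the
#'   rest).
#' @param seed Integer seed.
#' @return List with event tables \code{mutant_untreated},
#'   \code{mutant_treated}, \code{ref_untreated}, \code{ref_treated} and
#'   the true live mutant/reference fractions in \code{truth}.
#' @seealso [expectedGrowthRatio()] for the closed-form expectation.
#' @export
simulateCompetition <- function(rho_treated, rho_untreated = 1,
                                generations = 7, n_events = 20000,
                                gfp_loss_rate = 0.005,
                                background_fractions = c(dead = 0.01,
                                                         doublet = 0.02,
                                                         debris = 0.02),
                                seed = NULL) {
  assertScalarNumber(rho_treated, "rho_treated", lower = 0)
  assertScalarNumber(rho_untreated, "rho_untreated", lower = 0)
  assertScalarNumber(generations, "generations", lower = 0,
                     strict_lower = TRUE)
  mutant_frac <- function(rho)
    1 / (1 + 2^((1 - rho) * generations))
  bg <- background_fractions[c("dead", "doublet", "debris")]
  live <- 1 - sum(bg)
  mk <- function(f_neg, seed_off) {
    simulateFlowEvents(flowSimConfig(n_events,
      fractions = c(gfp_pos = live * (1 - f_neg),
                    gfp_neg = live * f_neg, bg),
      gfp_loss_rate = gfp_loss_rate,
      seed = if (is.null(seed)) NULL else seed + seed_off))
  }
  f_mu <- mutant_frac(rho_untreated)
  f_mt <- mutant_frac(rho_treated)
  f_r <- 0.5  # untagged wild type is neutral by construction
  list(mutant_untreated = mk(f_mu, 1L),
       mutant_treated = mk(f_mt, 2L),
       ref_untreated = mk(f_r, 3L),
       ref_treated = mk(f_r, 4L),
       truth = list(mutant_frac_untreated = f_mu,
                    mutant_frac_treated = f_mt,
                    ref_frac = f_r))
}

#' Closed-form expected growth ratio for the competition model
#'
#' Under the exponential competition model of [simulateCompetition()], a
#' sample whose live cells are a fraction \code{f} mutant has expected
#' scored GFP- fraction \code{W = f + (1 - f) * loss} (GFP+ cells scored
#' GFP- add to the numerator, and scored fractions sum to 1). The expected
#' growth ratio follows from the W_n formulas applied to these
#' expectations.
#'
#' @inheritParams simulateCompetition
#' @return Expected growth ratio (a single number).
#' @export
expectedGrowthRatio <- function(rho_treated, rho_untreated = 1,
                                generations = 7, gfp_loss_rate = 0.005) {
  f <- function(rho) 1 / (1 + 2^((1 - rho) * generations))
  w <- function(fr) fr + (1 - fr) * gfp_loss_rate
  w_n <- w(f(rho_untreated)) / w(0.5)
  w_n_star <- w(f(rho_treated)) / w(0.5)
  w_n_star / w_n
}
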