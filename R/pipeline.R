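#' Pipeline configuration
#'
#' Collects all stage parameters for a reproducible synthetic-screen run:
#' pool and sequencing settings, scoring constants, calling and enrichment
#' parameters, and the master seed. Every run writes its fully-resolved
#' configuration and a provenance block next to its outputs.
#'
#' @param seed Master integer seed; each stochastic stage derives its own
#'   seed from it.
#' @param n_mutants Pool size.
#' @param n_planted Number of mutants planted as sensitive.
#' @param planted_rho Relative growth rate of planted mutants under
#'   treatment.
#' @param depth Reads per sample.
#' @param n_screens Independent screens.
#' @param doublings Pool doublings g.
#' @param pseudocount Count pseudocount for frequencies.
#' @param fdr_cutoff Tail-area FDR cutoff for sensitivity calls.
#' @param pi0 Null proportion for [tailFDR()].
#' @param rho_jitter_sd Per-screen lognormal jitter on rho.
#' @param n_terms,term_size_range Annotation simulation settings.
#' @param enrich_alpha Corrected-p cutoff for enrichment.
#' @param use_reads When \code{TRUE}, counts are obtained by simulating
#'   FASTQ reads and re-counting them through the barcode matcher
#'   (slower); otherwise multinomial counts are drawn directly.
#' @param error_rate,max_mismatch Read simulation / matching parameters
#'   when \code{use_reads} is \code{TRUE}.
#' @return A list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(seed = 1, n_mutants = 2000, n_planted = 30,
                           planted_rho = 0.5, depth = 2e6, n_screens = 2,
                           doublings = 5, pseudocount = 0.5,
                           fdr_cutoff = 0.1, pi0 = 1,
                           rho_jitter_sd = 0.02, n_terms = 20,
                           term_size_range = c(5, 40),
                           enrich_alpha = 0.01, use_reads = FALSE,
                           error_rate = 0.001, max_mismatch = 1) {
  cfg <- list(seed = seed, n_mutants = n_mutants, n_planted = n_planted,
              planted_rho = planted_rho, depth = depth,
              n_screens = n_screens, doublings = doublings,
              pseudocount = pseudocount, fdr_cutoff = fdr_cutoff,
              pi0 = pi0, rho_jitter_sd = rho_jitter_sd, n_terms = n_terms,
              term_size_range = term_size_range,
              enrich_alpha = enrich_alpha, use_reads = use_reads,
              error_rate = error_rate, max_mismatch = max_mismatch)
  required <- c("seed", "n_mutants", "doublings", "depth", "fdr_cutoff")
  for (nm in required)
    if (is.null(cfg[[nm]]) || !is.finite(cfg[[nm]]))
      stop("pipeline config field missing or invalid: '", nm, "'")
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Fields missing from the file fall back to the [pipelineConfig()]
#' defaults; unknown fields are rejected.
#'
#' @param path YAML file.
#' @return A \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown pipeline config field(s): ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, vals)
}

#' Run the synthetic screen pipeline end to end
#'
#' Executes simulate -> (optionally sequence and count) -> score -> call
#' -> enrich -> cluster on a synthetic pool with planted sensitive
#' mutants, writing all tables, trees, a recovery report and a provenance
#' block into one run directory. Identical config and seed give identical
#' outputs.
#'
#' @param config A [pipelineConfig()].
#' @param outdir Run directory (created; must not exist unless
#'   \code{overwrite}).
#' @param overwrite Allow writing into an existing directory.
#' @return Invisibly, a list with the main in-memory results:
#'   \code{scores} (per-screen DataFrames), \code{calls}, \code{enrichment},
#'   \code{clustering}, \code{recovery}.
#' @export
runPipeline <- function(config, outdir, overwrite = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (dir.exists(outdir) && !overwrite)
    stop("output directory exists: ", outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  logline <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## simulate
  truth <- stage("simulate", {
    rho <- rep(1, config$n_mutants)
    planted <- integer(0)
    if (config$n_planted > 0) {
      planted <- seq_len(config$n_planted)
      rho[planted] <- config$planted_rho
    }
    pool_cfg <- poolSimConfig(config$n_mutants, rho = rho,
      doublings = config$doublings,
      rho_jitter_sd = config$rho_jitter_sd, seed = config$seed)
    screens <- if (config$use_reads) {
      lib <- simulateBarcodeLibrary(config$n_mutants,
                                    seed = config$seed + 1L)
      lapply(seq_len(config$n_screens), function(s) {
        ab <- simulatePool(pool_cfg)
        lapply(stats::setNames(c("control", "treatment"),
                               c("control", "treatment")), function(cond) {
          sim <- simulateReads(ab[[cond]], lib,
            readSimConfig(config$depth, config$error_rate,
                          seed = config$seed + 10L * s +
                            (cond == "treatment")))
          suppressMessages(countBarcodes(sim$reads, lib,
            max_mismatch = config$max_mismatch,
            sample_id = sprintf("screen%d_%s", s, cond),
            condition = cond))
        })
      })
    } else {
      simulateScreenCounts(pool_cfg, depth = config$depth,
                           n_screens = config$n_screens,
                           seed = config$seed + 2L)
    }
    logline("simulate: %d mutants, %d planted, %d screens, depth %g",
            config$n_mutants, config$n_planted, config$n_screens,
            config$depth)
    list(screens = screens, planted = planted)
  })

  ## score and call
  scores <- stage("score", {
    lapply(seq_along(truth$screens), function(s) {
      sc <- scoreScreen(truth$screens[[s]]$control,
                        truth$screens[[s]]$treatment,
                        doublings = config$doublings,
                        pseudocount = config$pseudocount,
                        pi0 = config$pi0)
      utils::write.table(as.data.frame(sc),
        file.path(outdir, sprintf("scores_screen%d.tsv", s)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      logline("score: screen %d, %d mutants", s, nrow(sc))
      sc
    })
  })
  calls <- stage("call", {
    qmat <- do.call(cbind, lapply(scores, function(s) s$q))
    rownames(qmat) <- scores[[1]]$mutant
    cl <- callSensitive(qmat, cutoff = config$fdr_cutoff)
    gi_mean <- rowMeans(do.call(cbind, lapply(scores, `[[`, "gi")))
    cl$gi_mean <- gi_mean
    cl$expressivity <- classifyExpressivity(cl$call, gi_mean)
    utils::write.table(cbind(mutant = rownames(cl), as.data.frame(cl)),
      file.path(outdir, "sensitivity_calls.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    logline("call: %d sensitive_both / %d mutants",
            sum(cl$call == "sensitive_both"), nrow(cl))
    cl
  })

  ## enrichment against a simulated annotation set with a planted term
  enr <- stage("enrich", {
    genes <- scores[[1]]$mutant
    hits <- rownames(calls)[calls$call == "sensitive_both"]
    planted_term <- NULL
    if (length(hits) >= 3)
      planted_term <- list(name = "planted_pathway",
        list_genes = hits,
        term_size = min(length(hits), 12),
        overlap = min(length(hits), 8))
    ann <- simulateAnnotations(genes, n_terms = config$n_terms,
      term_size_range = config$term_size_range,
      planted_term = planted_term, seed = config$seed + 3L)
    if (length(hits) == 0) {
      logline("enrich: no called genes, skipped")
      NULL
    } else {
      res <- enrichTerms(hits, ann, alpha = config$enrich_alpha)
      writeEnrichment(res, file.path(outdir, "enrichment.tsv"))
      logline("enrich: %d/%d terms significant at %.3g",
              sum(res$significant), nrow(res), config$enrich_alpha)
      res
    }
  })

  ## clustering of the called mutants' GI profiles across screens
  clu <- stage("cluster", {
    sel <- calls$call != "not_sensitive"
    if (sum(sel) >= 2 && length(scores) >= 2) {
      gi_mat <- do.call(cbind, lapply(scores, `[[`, "gi"))
      rownames(gi_mat) <- scores[[1]]$mutant
      colnames(gi_mat) <- sprintf("screen%d", seq_along(scores))
      bc <- clusterBidimensional(gi_mat[sel, , drop = FALSE])
      writeClusterFiles(bc, file.path(outdir, "gi_cluster"))
      logline("cluster: %d mutants x %d screens", sum(sel), ncol(gi_mat))
      bc
    } else {
      logline("cluster: skipped (< 2 called mutants or < 2 screens)")
      NULL
    }
  })

  ## recovery report against the planted truth
  recovery <- stage("report", {
    planted_ids <- scores[[1]]$mutant[truth$planted]
    called_ids <- rownames(calls)[calls$call == "sensitive_both"]
    rec <- list(
      n_planted = length(planted_ids),
      n_called = length(called_ids),
      n_recovered = length(intersect(planted_ids, called_ids)),
      false_positives = length(setdiff(called_ids, planted_ids)))
    rec$recovery_rate <- if (rec$n_planted > 0)
      rec$n_recovered / rec$n_planted else NA_real_
    jsonlite::write_json(rec, file.path(outdir, "recovery.json"),
                         auto_unbox = TRUE, digits = NA)
    logline("report: recovered %d/%d planted, %d false positives",
            rec$n_recovered, rec$n_planted, rec$false_positives)
    rec
  })

  ## provenance
  prov <- list(
    package = "barseqtox",
    version = as.character(utils::packageVersion("barseqtox")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config))
  prov$config_hash <- sum(utf8ToInt(paste(
    names(prov$config), vapply(prov$config, paste, character(1),
                               collapse = ","), collapse = "|")))
  yaml::write_yaml(prov, file.path(outdir, "provenance.yaml"))

  invisible(list(scores = scores, calls = calls, enrichment = enr,
                 clustering = clu, recovery = recovery))
}
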