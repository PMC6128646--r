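#' Match barcode windows to a library by Hamming distance
#'
#' Assigns each extracted barcode to the unique library barcode within
#' Hamming distance \code{max_mismatch}; returns \code{NA} (unassigned)
#' when no library barcode is close enough or when two or more are tied at
#' the minimum distance. Only substitutions are considered: barcode
#' sequencing errors are substitution-dominated and indels would shift the
#' fixed read layout anyway.
#'
#' @param barcode_seqs Character vector (or \code{DNAStringSet}) of
#'   extracted barcode windows, each exactly as long as the library
#'   barcodes.
#' @param library A [BarcodeLibrary-class].
#' @param max_mismatch Maximum Hamming distance (default 1).
#' @return Character vector of mutant ids, \code{NA} for unassigned, with
#'   attribute \code{"reason"} (\code{"assigned"}, \code{"no_match"},
#'   \code{"ambiguous"}, or \code{"bad_length"}).
#'
#' @details Matching proceeds by iterative deepening: exact hash lookup
#'   first, then lookup of all Hamming-d neighborhoods of the still
#'   unassigned windows for d = 1, 2, ... up to \code{max_mismatch}. A
#'   window matching two different mutants at its minimal distance is left
#'   unassigned (conservative tie rule), including windows equal to a
#'   duplicated library barcode.
#'
#' @examples
#' lib <- barcodeLibrary(c(m1 = "AAAA", m2 = "TTTT"))
#' matchBarcode(c("AAAA", "AAAT", "AATT"), lib, max_mismatch = 1)
#' @export
matchBarcode <- function(barcode_seqs, library, max_mismatch = 1) {
  stopifnot(methods::is(library, "BarcodeLibrary"))
  assertScalarNumber(max_mismatch, "max_mismatch", lower = 0)
  bc <- as.character(barcodes(library))
  ids <- mutantIds(library)
  L <- nchar(bc[1])
  q <- toupper(as.character(barcode_seqs))
  n <- length(q)
  out <- rep(NA_character_, n)
  reason <- rep("no_match", n)
  bad <- is.na(q) | nchar(q) != L
  reason[bad] <- "bad_length"

  # duplicated library barcodes can never be assigned unambiguously
  dup_bc <- unique(bc[duplicated(bc)])
  lut <- stats::setNames(ids, bc)
  lut[dup_bc] <- NA_character_

  pending <- which(!bad)
  for (d in 0:max_mismatch) {
    if (length(pending) == 0) break
    uq <- unique(q[pending])
    if (d == 0) {
      hit <- lut[uq]
      assigned <- stats::setNames(hit, uq)
      amb <- stats::setNames(uq %in% dup_bc, uq)
    } else {
      nb <- hammingNeighborhood(uq, d)
      hit_idx <- match(nb$variant, bc)
      keep <- !is.na(hit_idx)
      # matches at distance < d were already consumed in earlier rounds
      src <- nb$origin[keep]
      mid <- ids[hit_idx[keep]]
      exact_dup <- bc[hit_idx[keep]] %in% dup_bc
      mid[exact_dup] <- NA_character_
      matches <- split(mid, src)
      matches <- lapply(matches, unique)
      assigned <- vapply(matches, function(v)
        if (length(v) == 1 && !is.na(v)) v else NA_character_, character(1))
      amb <- vapply(matches, function(v)
        length(v) > 1 || anyNA(v), logical(1))
      miss <- setdiff(uq, names(assigned))
      assigned[miss] <- NA_character_
      amb[miss] <- FALSE
    }
    res <- assigned[q[pending]]
    isamb <- amb[q[pending]]
    hitpos <- !is.na(res) | isamb
    out[pending[!is.na(res)]] <- res[!is.na(res)]
    reason[pending[!is.na(res)]] <- "assigned"
    reason[pending[which(isamb & is.na(res))]] <- "ambiguous"
    pending <- pending[!hitpos]
  }
  attr(out, "reason") <- reason
  out
}

# All sequences at Hamming distance exactly d from each query (d in 1:2
# enumerated combinatorially; d > 2 falls back to recursive expansion).
# Returns data.frame(origin, variant); variants that equal the origin or
# collide across substitution choices are not deduplicated -- callers
# match against a library and unique() per origin.
hammingNeighborhood <- function(queries, d) {
  L <- nchar(queries[1])
  bases <- c("A", "C", "G", "T")
  one_sub <- function(origins, seqs) {
    n <- length(seqs)
    org <- rep(origins, each = L * 3L)
    pos <- rep(rep(seq_len(L), each = 3L), times = n)
    # for each sequence, each position, the 3 alternative bases
    cur <- substring(rep(seqs, each = L * 3L), pos, pos)
    repl <- matrix(c("C", "G", "T",
                     "A", "G", "T",
                     "A", "C", "T",
                     "A", "C", "G"), nrow = 3)
    colnames(repl) <- bases
    which_alt <- rep_len(seq_len(3), length(pos))
    newbase <- repl[cbind(which_alt,
                          match(cur, bases, nomatch = 1L))]
    pre <- substring(rep(seqs, each = L * 3L), 1L, pos - 1L)
    post <- substring(rep(seqs, each = L * 3L), pos + 1L, L)
    data.frame(origin = org, variant = paste0(pre, newbase, post),
               stringsAsFactors = FALSE)
  }
  nb <- one_sub(queries, queries)
  dd <- 1L
  while (dd < d) {
    nb <- one_sub(nb$origin, nb$variant)
    dd <- dd + 1L
  }
  nb
}

#' Count barcode reads per mutant
#'
#' One pass over a read set: extracts the barcode window declared by the
#' layout (fixed offset from the read start, or 5'-flank anchoring),
#' assigns it with [matchBarcode()], and tallies per-mutant counts.
#'
#' @param reads A \code{DNAStringSet}, character vector of read sequences,
#'   or path to a FASTQ file (optionally gzipped).
#' @param library A [BarcodeLibrary-class].
#' @param layout A [readLayout()] declaring the barcode window.
#' @param max_mismatch Maximum Hamming distance for assignment (default 1).
#' @param sample_id,condition Sample annotations stored in the result.
#' @param anchor When \code{TRUE}, locate the barcode by exact match of the
#'   5' flank instead of a fixed offset (reads whose flank is not found are
#'   unassigned).
#' @return A [CountTable-class]. The assignment rate is reported with
#'   \code{message()}.
#'
#' @examples
#' lib <- simulateBarcodeLibrary(3, seed = 1)
#' sim <- simulateReads(c(1, 1, 2), lib, readSimConfig(60, 0, seed = 2))
#' ct <- countBarcodes(sim$reads, lib)
#' mutantCounts(ct)
#' @export
countBarcodes <- function(reads, library, layout = readLayout(),
                          max_mismatch = 1, sample_id = "sample",
                          condition = "control", anchor = FALSE) {
  stopifnot(methods::is(library, "BarcodeLibrary"),
            inherits(layout, "ReadLayout"))
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- readFastq(reads)
  seqs <- as.character(reads)
  total <- length(seqs)
  if (total == 0) {
    warning("empty read stream: returning an all-zero count table")
    hits <- character(0)
  } else {
    off <- nchar(layout$flank5)
    blen <- layout$barcode_length
    if (anchor) {
      pos <- regexpr(layout$flank5, seqs, fixed = TRUE)
      start <- ifelse(pos > 0, pos + off, NA_integer_)
    } else {
      start <- rep(off + 1L, total)
    }
    window <- substring(seqs, start, start + blen - 1L)
    window[is.na(start) | nchar(window) < blen] <- ""  # -> bad_length
    hits <- matchBarcode(window, library, max_mismatch = max_mismatch)
  }
  tab <- table(factor(hits, levels = mutantIds(library)))
  counts <- stats::setNames(as.integer(tab), mutantIds(library))
  unassigned <- total - sum(counts)
  message(sprintf("assigned %d/%d reads (%.2f%%)", sum(counts), total,
                  if (total > 0) 100 * sum(counts) / total else 0))
  methods::new("CountTable", counts = counts,
    genes = unname(geneNames(library)), sample_id = sample_id,
    condition = condition, unassigned = as.integer(unassigned),
    total_reads = as.integer(total))
}

#' @rdname CountTable-class
#' @export
setMethod("mutantCounts", "CountTable", function(x) x@counts)

#' @rdname CountTable-class
#' @export
setMethod("unassignedReads", "CountTable", function(x) x@unassigned)

#' @rdname CountTable-class
#' @export
setMethod("length", "CountTable", function(x) length(x@counts))

#' @rdname CountTable-class
#' @export
setMethod("show", "CountTable", function(object) {
  cat("CountTable", object@sample_id, "(", object@condition, "):",
      length(object@counts), "mutants,", sum(object@counts),
      "assigned +", object@unassigned, "unassigned reads\n")
})

#' Read or write a CountTable as TSV
#'
#' Columns \code{mutant_id}, \code{gene}, \code{count}; the unassigned
#' tally is written as a final row with id \code{*unassigned*}.
#'
#' @param x A \code{CountTable} (for writing).
#' @param path File path.
#' @param sample_id,condition Annotations applied on reading.
#' @return \code{readCountTable} returns a \code{CountTable};
#'   \code{writeCountTable} returns \code{path} invisibly.
#' @export
writeCountTable <- function(x, path) {
  stopifnot(methods::is(x, "CountTable"))
  df <- data.frame(mutant_id = c(names(x@counts), "*unassigned*"),
    gene = c(x@genes, ""), count = c(unname(x@counts), x@unassigned))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountTable
#' @export
readCountTable <- function(path, sample_id = "sample",
                           condition = "control") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  un <- df$mutant_id == "*unassigned*"
  unassigned <- if (any(un)) as.integer(sum(df$count[un])) else 0L
  df <- df[!un, ]
  methods::new("CountTable",
    counts = stats::setNames(as.integer(df$count), df$mutant_id),
    genes = as.character(df$gene), sample_id = sample_id,
    condition = condition, unassigned = unassigned,
    total_reads = as.integer(sum(df$count) + unassigned))
}

#' Bind count tables into a SummarizedExperiment
#'
#' Assembles samples (columns) over the union of mutants (rows), with
#' sample id, condition, screen, unassigned and total reads in
#' \code{colData} and gene names in \code{rowData}. Mutants absent from a
#' sample's library version get \code{NA} counts.
#'
#' @param count_tables List of [CountTable-class] objects.
#' @param screen Character or integer vector assigning each sample to a
#'   screen (recycled).
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{"counts"}.
#' @export
bindScreens <- function(count_tables, screen = seq_along(count_tables)) {
  stopifnot(length(count_tables) > 0,
            all(vapply(count_tables, methods::is, logical(1), "CountTable")))
  screen <- rep_len(as.character(screen), length(count_tables))
  all_ids <- unique(unlist(lapply(count_tables,
                                  function(x) names(x@counts))))
  mat <- vapply(count_tables, function(x) {
    v <- rep(NA_integer_, length(all_ids))
    v[match(names(x@counts), all_ids)] <- x@counts
    v
  }, integer(length(all_ids)))
  mat <- matrix(mat, nrow = length(all_ids),
                dimnames = list(all_ids,
                  vapply(count_tables, function(x) x@sample_id,
                         character(1))))
  genes <- rep(NA_character_, length(all_ids))
  for (x in count_tables)
    genes[match(names(x@counts), all_ids)] <- x@genes
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = mat),
    rowData = S4Vectors::DataFrame(gene = genes, row.names = all_ids),
    colData = S4Vectors::DataFrame(
      sample_id = colnames(mat),
      condition = vapply(count_tables, function(x) x@condition,
                         character(1)),
      screen = screen,
      unassigned = vapply(count_tables, function(x) x@unassigned,
                          integer(1)),
      total_reads = vapply(count_tables, function(x) x@total_reads,
                           integer(1))))
}
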