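#' Read layout for barcode sequencing
#'
#' Fixed flanking sequences around the strain barcode. A simulated or real
#' read is \code{flank5 | barcode | flank3}; the barcode window starts at
#' offset \code{nchar(flank5)} from the read start.
#'
#' @param flank5,flank3 Fixed sequences 5' and 3' of the barcode.
#' @param barcode_length Barcode length in nt (default 20).
#' @return A list of class \code{ReadLayout}.
#' @export
readLayout <- function(flank5 = "GATGTCCACGAGGTCTCT",
                       flank3 = "CGTA",
                       barcode_length = 20) {
  stopifnot(is.character(flank5), is.character(flank3))
  assertScalarNumber(barcode_length, "barcode_length", lower = 1)
  structure(list(flank5 = toupper(flank5), flank3 = toupper(flank3),
                 barcode_length = as.integer(barcode_length)),
            class = "ReadLayout")
}

#' Configuration for simulated barcode sequencing
#'
#' @param depth Total number of reads to draw for the sample.
#' @param substitution_error_rate Per-base substitution probability,
#'   in \code{[0, 0.25)}.
#' @param layout A [readLayout()].
#' @param seed Integer seed.
#' @return A list of class \code{ReadSimConfig}.
#' @export
readSimConfig <- function(depth, substitution_error_rate = 0.001,
                          layout = readLayout(), seed = NULL) {
  assertScalarNumber(depth, "depth", lower = 1)
  assertScalarNumber(substitution_error_rate, "substitution_error_rate",
                     lower = 0, upper = 0.25 - 1e-12)
  stopifnot(inherits(layout, "ReadLayout"))
  structure(list(depth = as.integer(depth),
                 substitution_error_rate = substitution_error_rate,
                 layout = layout, seed = seed),
            class = "ReadSimConfig")
}

#' Simulate barcode sequencing reads
#'
#' Draws the per-mutant read counts from a multinomial distribution at the
#' configured depth, assembles each read as \code{flank5|barcode|flank3},
#' and applies i.i.d. base substitution errors at the configured rate
#' (an erroneous base is always replaced by a different base).
#'
#' @param abundances Relative abundances, one per library mutant
#'   (normalized internally).
#' @param library A [BarcodeLibrary-class] aligned with \code{abundances}.
#' @param config A [readSimConfig()].
#' @return A list with \code{reads} (a named \code{DNAStringSet}) and
#'   \code{true_counts} (the multinomial draw, named by mutant id).
#'
#' @examples
#' lib <- simulateBarcodeLibrary(5, seed = 1)
#' sim <- simulateReads(rep(0.2, 5), lib, readSimConfig(100, 0, seed = 1))
#' sim$true_counts
#' @export
simulateReads <- function(abundances, library, config) {
  stopifnot(methods::is(library, "BarcodeLibrary"),
            inherits(config, "ReadSimConfig"))
  if (length(abundances) != length(library))
    stop("'abundances' must align with the library entries")
  if (any(!is.finite(abundances)) || any(abundances < 0) ||
      sum(abundances) <= 0)
    stop("'abundances' must be non-negative with positive sum")
  bc <- as.character(barcodes(library))
  if (anyDuplicated(bc))
    warning("library contains identical barcodes; ",
            "their reads cannot be assigned unambiguously")
  withSeed(config$seed, {
    counts <- as.integer(stats::rmultinom(1, size = config$depth,
                                          prob = abundances / sum(abundances)))
    names(counts) <- mutantIds(library)
    lay <- config$layout
    seqs <- rep(paste0(lay$flank5, bc, lay$flank3), counts)
    if (config$substitution_error_rate > 0 && length(seqs) > 0)
      seqs <- substituteBases(seqs, config$substitution_error_rate)
    reads <- Biostrings::DNAStringSet(seqs)
    if (length(reads) > 0)
      names(reads) <- sprintf("read%07d", seq_along(reads))
    list(reads = reads, true_counts = counts)
  })
}

# Apply i.i.d. substitution errors to equal-length sequences.
# Each hit base is replaced by one of the three other bases uniformly.
substituteBases <- function(seqs, rate) {
  L <- nchar(seqs[1])
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = L)
  hit <- which(stats::runif(length(m)) < rate)
  if (length(hit) > 0) {
    bases <- c("A", "C", "G", "T")
    idx <- match(m[hit], bases)
    idx[is.na(idx)] <- sample.int(4, sum(is.na(idx)), replace = TRUE) # N etc.
    shift <- sample.int(3, length(hit), replace = TRUE)
    m[hit] <- bases[((idx - 1 + shift) %% 4) + 1]
  }
  do.call(paste0, split(m, slice.index(m, 1)))
}

#' Write or read FASTQ
#'
#' Minimal plain-text 4-line-per-record FASTQ support for simulated reads.
#' Reading delegates to \code{Biostrings::readDNAStringSet}.
#'
#' @param reads A \code{DNAStringSet} (names become read ids).
#' @param path Output/input file path.
#' @param quality_char Single character used for every base quality.
#' @return \code{writeFastq} returns \code{path} invisibly;
#'   \code{readFastq} returns a \code{DNAStringSet}.
#' @export
writeFastq <- function(reads, path, quality_char = "I") {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%07d", seq_along(reads))
  seqs <- as.character(reads)
  qual <- vapply(nchar(seqs), function(n)
    paste(rep(quality_char, n), collapse = ""), character(1))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  invisible(path)
}

#' @rdname writeFastq
#' @export
readFastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}
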