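#' @keywords internal
"_PACKAGE"

#' @useDynLib ssrpipe, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods as is
#' @importFrom stats dist hclust rbeta rbinom rgamma runif var pnorm as.dist
#' @importFrom utils combn read.delim write.table head
NULL

# Evaluate `code` under a fixed RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Reverse complement of character vectors of DNA (keeps N).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop2(name, " must be a single proportion in [0, 1]")
  x
}

# ---- lightweight FASTQ container -------------------------------------------

#' Construct a set of sequencing reads
#'
#' A minimal container for (single-end) FASTQ records: parallel character
#' vectors of identifiers, sequences, and phred+33 quality strings.
#'
#' @param id,seq,qual equal-length character vectors.
#' @return An object of class `fastq_reads`.
#' @export
fastq_reads <- function(id, seq, qual) {
  if (length(id) != length(seq) || length(seq) != length(qual))
    stop2("id, seq and qual must have equal length")
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop2("sequence/quality length mismatch at record ", bad[1L])
  structure(list(id = as.character(id), seq = toupper(as.character(seq)),
                 qual = as.character(qual)),
            class = "fastq_reads")
}

#' @export
length.fastq_reads <- function(x) length(x$seq)

#' @export
print.fastq_reads <- function(x, ...) {
  cat("fastq_reads:", length(x), "records,",
      if (length(x)) paste0("read length ", min(nchar(x$seq)), "-",
                            max(nchar(x$seq))) else "", "\n")
  invisible(x)
}

#' Read a FASTQ file
#'
#' @param path file path (uncompressed or gzipped).
#' @return A [fastq_reads] object.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop2("malformed FASTQ (", path, "): ", length(lines),
          " lines is not a multiple of 4")
  n <- length(lines) %/% 4L
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- lines[seq(2L, by = 4L, length.out = n)]
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  ql <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+"))
  if (length(bad))
    stop2("malformed FASTQ (", path, ") at record ", bad[1L],
          ": missing @/+ header")
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad))
    stop2("malformed FASTQ (", path, ") at record ", bad[1L],
          ": sequence and quality lengths differ")
  fastq_reads(sub("^@", "", hd), sq, ql)
}

#' Write a FASTQ file
#'
#' @param reads a [fastq_reads] object.
#' @param path output file path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "fastq_reads"))
  out <- character(4L * length(reads))
  out[seq(1L, by = 4L, length.out = length(reads))] <- paste0("@", reads$id)
  out[seq(2L, by = 4L, length.out = length(reads))] <- reads$seq
  out[seq(3L, by = 4L, length.out = length(reads))] <- "+"
  out[seq(4L, by = 4L, length.out = length(reads))] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Read/write FASTA scaffold sets
#'
#' Thin wrappers around Biostrings keeping the package's container
#' (a named `DNAStringSet`) explicit.
#'
#' @param path file path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop2("empty FASTA file: ", path)
  x
}

#' @param x a `DNAStringSet` or named character vector.
#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  if (!is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# ---- TSV with schema header -------------------------------------------------

# Every pipeline TSV carries a "# columns:" header comment.
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste0("# columns: ", paste(names(df), collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = ".")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             na.strings = ".", check.names = FALSE, ...)
}
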