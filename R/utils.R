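#' @useDynLib vectortrace, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbinom rexp rpois runif median setNames
#' @importFrom utils write.table read.delim
NULL

DNA_ALPHABET <- c("A", "C", "G", "T")

## All internal coordinates are 0-based, half-open. Conversion to/from the
## 1-based SAM convention happens only in the SAM reader/writer and in
## parse_sa_tag.

is_dna <- function(x) {
  is.character(x) && length(x) == 1L && nzchar(x) &&
    !grepl("[^ACGT]", x)
}

assert_dna <- function(x, what = deparse(substitute(x))) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop("invalid-sequence: ", what, " must be a nonempty DNA string", call. = FALSE)
  }
  if (grepl("[^ACGT]", x)) {
    stop("invalid-sequence: ", what, " contains non-ACGT characters", call. = FALSE)
  }
  invisible(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
}

## Run code with a locally seeded RNG, restoring the caller's RNG state.
## Every stochastic operation in the package takes an explicit seed and
## routes through this, so identical seeds give byte-identical output.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## genome containers: a named character vector of contig sequences is the
## light internal representation; Biostrings does the FASTA IO.

as_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    seqs <- as.character(x)
    names(seqs) <- names(x)
    return(seqs)
  }
  if (is.character(x)) {
    if (is.null(names(x)) && length(x) > 0L) {
      stop("genome contigs must be named", call. = FALSE)
    }
    return(x)
  }
  stop("genome must be a named character vector or DNAStringSet", call. = FALSE)
}

#' Read a (multi-)FASTA file into a named character vector of contigs
#' @param path path to a FASTA file
#' @return named character vector, one element per contig
#' @export
read_fasta <- function(path) {
  as_genome(Biostrings::readDNAStringSet(path))
}

#' Write contigs to FASTA (wrapped at 60 columns)
#' @param genome named character vector of contig sequences
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Write reads to FASTQ (Phred+33, constant Q20 qualities)
#' @param reads named character vector of read sequences (names become ids)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fastq <- function(reads, path) {
  if (length(reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  qual <- vapply(nchar(reads), function(n) strrep("5", n), "")  # "5" = Q20
  lines <- as.vector(rbind(paste0("@", ids), unname(reads), "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#' @param path FASTQ path
#' @return named character vector of read sequences
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

interval_ok <- function(iv) {
  is.numeric(iv) && length(iv) == 2L && !anyNA(iv) && iv[1] <= iv[2]
}

## lower median of an integer vector (ties broken downward)
lower_median <- function(x) {
  x <- sort(x)
  x[(length(x) + 1L) %/% 2L]
}
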