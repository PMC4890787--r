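#' Simulate single-end reads from a haplotype
#'
#' Uniformly positioned, forward-orientation reads from a toy haplotype, with
#' independent per-base substitution errors. The read count is
#' `round(coverage * length / read_len)`; a very low coverage may legitimately
#' produce zero reads. Base qualities are constant (the generator does not
#' model quality, only substitution errors).
#'
#' @param hap A [toy_genome()] (typically a derived haplotype).
#' @param read_len Read length in bases (`<=` haplotype length).
#' @param coverage Expected fold coverage (`> 0`).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return A named character vector of read sequences (names are read ids),
#'   with attribute `positions` giving 1-based start positions on `hap`.
#' @export
simulate_junction_reads <- function(hap, read_len = 150L, coverage = 30,
                                    error_rate = 0.001, seed = 1L) {
  stopifnot(inherits(hap, "toy_genome"))
  if (coverage <= 0) stop("coverage must be > 0")
  if (read_len > hap$length) stop("read_len exceeds haplotype length")
  stopifnot(error_rate >= 0, error_rate < 1)
  set.seed(seed)
  n <- round(coverage * hap$length / read_len)
  if (n == 0L) {
    out <- character(0)
    attr(out, "positions") <- integer(0)
    return(out)
  }
  starts <- sample.int(hap$length - read_len + 1L, n, replace = TRUE)
  reads <- substring(hap$sequence, starts, starts + read_len - 1L)
  if (error_rate > 0) {
    n_err <- stats::rbinom(n, read_len, error_rate)
    for (i in which(n_err > 0)) {
      pos <- sample.int(read_len, n_err[i])
      r <- reads[i]
      for (p in pos) {
        cur <- substr(r, p, p)
        substr(r, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      }
      reads[i] <- r
    }
  }
  names(reads) <- sprintf("read_%06d", seq_len(n))
  attr(reads, "positions") <- starts
  reads
}

#' Write reads as FASTQ
#'
#' @param reads Named character vector of read sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(as.character(reads))
  names(x) <- if (is.null(names(reads))) {
    sprintf("read_%06d", seq_along(reads))
  } else names(reads)
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(reads)))
  )
  invisible(path)
}

#' Read a FASTQ file into a read vector
#'
#' @param path FASTQ file.
#' @return Named character vector of read sequences.
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- names(x)
  out
}
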