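#' Normalize a sequence to the RNA alphabet
#'
#' Uppercases and converts T to U. The package's internal alphabet for tags
#' and mature miRNAs is RNA; DNA-alphabet input from FASTA/FASTQ files is
#' normalized on read.
#'
#' @param x character vector of sequences.
#' @return character vector in the RNA alphabet.
#' @export
norm_rna <- function(x) chartr("acgtuT", "ACGUUU", x)

#' Normalize a sequence to the DNA alphabet
#'
#' @param x character vector of sequences.
#' @return character vector in the DNA alphabet.
#' @export
norm_dna <- function(x) chartr("acgtuU", "ACGTTT", x)

#' Reverse complement of character sequences
#'
#' @param x character vector (DNA or RNA alphabet).
#' @param alphabet "dna" or "rna" output alphabet.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  y <- vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTU", "TGCAA", norm_dna(s)), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
  if (alphabet == "rna") norm_rna(y) else y
}

#' GC percentage of a sequence
#'
#' @param x character vector of sequences.
#' @return numeric vector, percentage of G+C bases (0-100).
#' @export
gc_percent <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  ifelse(n > 0, 100 * gc / n, NA_real_)
}

#' Percentage rounded half-up
#'
#' Table-style percentage: `part/whole * 100`, rounded *half-up* to
#' `decimals` digits (unlike [round()], which rounds half to even).
#'
#' @param part,whole counts; `whole` must be positive.
#' @param decimals digits to keep (default 2).
#' @return numeric percentage.
#' @export
percent <- function(part, whole, decimals = 2) {
  if (any(whole <= 0)) stop("percent(): 'whole' must be > 0")
  x <- part / whole * 100
  f <- 10^decimals
  floor(x * f + 0.5) / f
}

# random sequence with an exact GC count (internal)
random_seq <- function(length, gc = 0.5, alphabet = c("A", "C", "G", "U")) {
  # stochastic rounding keeps the expected GC unbiased at any length
  frac <- gc * length
  n_gc <- floor(frac) + (runif(1) < frac - floor(frac))
  bases <- c(sample(c("G", "C"), n_gc, replace = TRUE),
             sample(setdiff(alphabet, c("G", "C")), length - n_gc,
                    replace = TRUE))
  paste(sample(bases), collapse = "")
}
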