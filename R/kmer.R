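#' k-mer extraction parameters
#'
#' Bundles the word length \code{k} and the strand-handling mode used
#' everywhere a sequence is decomposed into k-mers. In canonical mode a
#' k-mer and its reverse complement are identified, and every word is
#' stored as the lexicographically smaller of the two; this makes
#' matching strand-agnostic, which is the natural choice for shotgun
#' reads. Non-canonical mode matches one strand literally.
#'
#' @param k Positive integer word length (default 18).
#' @param canonical Logical; identify a k-mer with its reverse
#'   complement (default \code{TRUE}).
#' @return An object of class \code{kmer_params}.
#' @examples
#' kmer_params(k = 18, canonical = TRUE)
#' @export
kmer_params <- function(k = 18L, canonical = TRUE) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 2L)
    stop("'k' must be a single integer >= 2", call. = FALSE)
  if (!is.logical(canonical) || length(canonical) != 1L || is.na(canonical))
    stop("'canonical' must be TRUE or FALSE", call. = FALSE)
  structure(list(k = k, canonical = canonical), class = "kmer_params")
}

#' @export
print.kmer_params <- function(x, ...) {
  cat(sprintf("<kmer_params> k = %d, %s\n", x$k,
              if (x$canonical) "canonical (strand-agnostic)" else
                "non-canonical (single strand)"))
  invisible(x)
}

same_params <- function(a, b) {
  a$k == b$k && a$canonical == b$canonical
}

#' Reverse complement of nucleotide strings
#'
#' Vectorized reverse complement over plain character strings restricted
#' to the A/C/G/T alphabet.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "AAC"))
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

canonicalize <- function(words) {
  if (length(words) == 0L) return(words)
  rc <- revcomp(words)
  smaller <- words <= rc
  ifelse(smaller, words, rc)
}

# Start positions (1-based) of windows made of A/C/G/T only; windows that
# overlap any other symbol (N, IUPAC codes, gaps) are skipped.
valid_window_starts <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(integer(0))
  ok <- strsplit(sequence, "", fixed = TRUE)[[1]] %in% c("A", "C", "G", "T")
  run <- cumsum(ok)
  starts <- seq_len(n - k + 1L)
  good <- (run[starts + k - 1L] - c(0L, run)[starts]) == k
  starts[good]
}

#' Extract the k-mer set of a sequence
#'
#' Slides a window of length \code{k} over the sequence and collects the
#' distinct words. Windows containing any symbol other than A/C/G/T
#' (e.g. N or other IUPAC degeneracy codes) are skipped rather than
#' failing, so draft genomes with ambiguous positions are handled; a
#' strict mode rejects such sequences outright. In canonical mode each
#' window is replaced by \code{min(window, revcomp(window))} before set
#' insertion. A sequence shorter than \code{k} yields the empty set.
#'
#' @param sequence A single nucleotide string (case-insensitive).
#' @param params A [kmer_params] object.
#' @param strict Logical; if \code{TRUE}, any non-A/C/G/T symbol in the
#'   sequence is an error instead of a skipped window.
#' @return An object of class \code{kmer_set}: a list with \code{words}
#'   (sorted character vector, set semantics) and \code{params}.
#' @examples
#' extract_kmers("ACGT", kmer_params(k = 3, canonical = FALSE))
#' extract_kmers("ACGNT", kmer_params(k = 3, canonical = FALSE))
#' @export
extract_kmers <- function(sequence, params = kmer_params(), strict = FALSE) {
  stopifnot(inherits(params, "kmer_params"))
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("'sequence' must be a single string", call. = FALSE)
  sequence <- toupper(sequence)
  if (strict && grepl("[^ACGT]", sequence))
    stop("sequence contains non-A/C/G/T symbols (strict mode)", call. = FALSE)
  starts <- valid_window_starts(sequence, params$k)
  words <- if (length(starts) == 0L) character(0) else
    substring(sequence, starts, starts + params$k - 1L)
  if (params$canonical) words <- canonicalize(words)
  kmer_set(sort(unique(words)), params)
}

kmer_set <- function(words, params) {
  structure(list(words = words, params = params), class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("<kmer_set> %d distinct %d-mers (%s)\n", length(x$words),
              x$params$k, if (x$params$canonical) "canonical" else "literal"))
  invisible(x)
}

#' @export
length.kmer_set <- function(x) length(x$words)

# Union of k-mer sets of several sequences under one parameter set.
kmers_of_sequences <- function(sequences, params, strict = FALSE) {
  words <- unlist(lapply(sequences, function(s)
    extract_kmers(s, params, strict = strict)$words), use.names = FALSE)
  kmer_set(sort(unique(words)), params)
}
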