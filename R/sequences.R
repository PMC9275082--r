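#' Read a FASTA file as a named character vector
#'
#' Reads nucleotide sequences (DNA or RNA alphabet) from a FASTA file.
#' Multi-line records are supported; the sequence identifier is the first
#' whitespace-delimited token of the header line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences, `U` mapped to `T`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids in ", path)
  normalize_sequences(seqs)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Normalize nucleotide sequences to the ACGT alphabet
#'
#' Uppercases and maps `U` to `T` so RNA and DNA inputs are treated uniformly.
#'
#' @param seqs Named character vector.
#' @param on_invalid What to do with sequences containing characters outside
#'   ACGT after mapping: `"fail"` stops, `"drop"` removes the offending records
#'   with a warning.
#' @return Named character vector over ACGT.
#' @export
normalize_sequences <- function(seqs, on_invalid = c("fail", "drop")) {
  on_invalid <- match.arg(on_invalid)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  if (anyDuplicated(names(seqs))) stop("sequence ids must be unique")
  out <- chartr("u", "T", toupper(seqs))
  out <- chartr("U", "T", out)
  bad <- grepl("[^ACGT]", out) | !nzchar(out)
  if (any(bad)) {
    msg <- paste0("sequences with characters outside ACGT (or empty): ",
                  paste(names(out)[bad], collapse = ", "))
    if (on_invalid == "fail") stop(msg)
    warning(msg, "; records dropped")
    out <- out[!bad]
  }
  out
}

#' Enumerate all k-mers in lexicographic order
#' @keywords internal
all_kmers <- function(k) {
  stopifnot(k >= 1)
  alpha <- c("A", "C", "G", "T")
  km <- alpha
  if (k > 1) {
    for (i in seq_len(k - 1L)) {
      km <- as.vector(t(outer(km, alpha, paste0)))
    }
  }
  sort(km)
}

#' Binary k-mer feature matrix
#'
#' Encodes each sequence as a length-`4^k` indicator vector over all k-mers in
#' lexicographic order: entry `(i, m)` is 1 iff k-mer `m` occurs at least once
#' in sequence `i`. With `mode = "frequency"` the relative frequency of each
#' k-mer among the sequence's windows is returned instead.
#'
#' Sequences shorter than `k` yield an all-zero row with a warning.
#'
#' @param seqs Named character vector of ACGT sequences
#'   (see [normalize_sequences()]).
#' @param k k-mer length (small positive integer; default 3 gives 64 features).
#' @param mode `"presence"` (binary, default) or `"frequency"`.
#' @return Numeric matrix with one row per sequence (rownames = ids) and
#'   `4^k` columns named by k-mer; attribute `k` records the k-mer length.
#' @examples
#' kmer_features(c(s1 = "ACGT", s2 = "AAAA"), k = 1)
#' @export
kmer_features <- function(seqs, k = 3L, mode = c("presence", "frequency")) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  seqs <- normalize_sequences(seqs)
  kmers <- all_kmers(k)
  F <- matrix(0, nrow = length(seqs), ncol = length(kmers),
              dimnames = list(names(seqs), kmers))
  short <- character(0)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    n <- nchar(s)
    if (n < k) {
      short <- c(short, names(seqs)[i])
      next
    }
    starts <- seq_len(n - k + 1L)
    wins <- substring(s, starts, starts + k - 1L)
    idx <- match(wins, kmers)
    tab <- tabulate(idx, nbins = length(kmers))
    F[i, ] <- if (mode == "presence") as.numeric(tab > 0) else tab / length(wins)
  }
  if (length(short))
    warning("sequences shorter than k=", k, " yield all-zero rows: ",
            paste(short, collapse = ", "))
  attr(F, "k") <- k
  attr(F, "mode") <- mode
  F
}
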