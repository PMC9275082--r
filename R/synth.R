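# Synthetic planted-block benchmark data. The generator encodes the premise
# the model exploits: miRNAs that share sequence motifs share targets. Each
# miRNA and target belongs to one of `n_blocks` communities; links are dense
# within a community and sparse across, and every community carries a private
# sequence motif so k-mer similarity is informative of community membership.

#' Configuration for the synthetic planted-block generator
#'
#' @param M,N Numbers of miRNAs and targets (defaults 60 and 200).
#' @param n_blocks Planted communities (default 4).
#' @param p_in,p_out Within-/between-block link probabilities (defaults 0.3
#'   and 0.01; must satisfy `p_out < p_in`).
#' @param seq_len_mirna,seq_len_target Sequence lengths (defaults 22 nt, the
#'   canonical mature-miRNA length, and 60 nt, a binding-site-centred target
#'   fragment; with binary 3-mer features, much longer fragments saturate all
#'   64 indicators and the Jaccard index stops discriminating blocks).
#' @param motif_strength Probability that each motif slot in a sequence
#'   carries the block motif (default 0.8); 0 removes the sequence signal.
#' @param motif_len Length of the block-specific motif (default 8 nt).
#' @param seed Integer seed; all outputs are reproducible from it.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(M = 60L, N = 200L, n_blocks = 4L,
                         p_in = 0.3, p_out = 0.01,
                         seq_len_mirna = 22L, seq_len_target = 60L,
                         motif_strength = 0.8, motif_len = 8L, seed = 1L) {
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1,
            n_blocks >= 1, n_blocks <= min(M, N),
            motif_strength >= 0, motif_strength <= 1,
            motif_len < seq_len_mirna)
  structure(list(M = as.integer(M), N = as.integer(N),
                 n_blocks = as.integer(n_blocks),
                 p_in = p_in, p_out = p_out,
                 seq_len_mirna = as.integer(seq_len_mirna),
                 seq_len_target = as.integer(seq_len_target),
                 motif_strength = motif_strength,
                 motif_len = as.integer(motif_len),
                 seed = as.integer(seed)),
            class = "synth_config")
}

rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

plant_motif <- function(seq, motif, n_slots, prob) {
  len <- nchar(seq)
  ml <- nchar(motif)
  if (n_slots < 1 || prob == 0 || len < ml) return(seq)
  starts <- sample.int(len - ml + 1L, n_slots,
                       replace = n_slots > (len - ml + 1L))
  for (st in starts) {
    if (stats::runif(1) < prob)
      substr(seq, st, st + ml - 1L) <- motif
  }
  seq
}

#' Generate a synthetic miRNA-target dataset with planted block structure
#'
#' Every miRNA and target is assigned to a community; associations are drawn
#' `Bernoulli(p_in)` within a community and `Bernoulli(p_out)` across, and
#' each sequence carries its community's motif at rate `motif_strength`, so
#' that held-out links are recoverable from the remaining links and the
#' sequence similarity. Empty communities trigger a re-draw of the
#' assignment.
#'
#' @param cfg A [synth_config()].
#' @return List with `mirna_seqs`, `target_seqs` (named character vectors,
#'   RNA alphabet), `pairs` (data.frame of positive pairs), `A` (association
#'   matrix), `mirna_blocks`, `target_blocks`, `motifs`, and `config`.
#' @export
synth_generate <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  B <- cfg$n_blocks
  repeat {
    mb <- sample.int(B, cfg$M, replace = TRUE)
    tb <- sample.int(B, cfg$N, replace = TRUE)
    if (all(seq_len(B) %in% mb) && all(seq_len(B) %in% tb)) break
  }
  # distinct block motifs (RNA alphabet)
  repeat {
    motifs <- vapply(seq_len(B), function(b) rand_seq(cfg$motif_len), "")
    if (!anyDuplicated(motifs)) break
  }
  mirna_ids <- sprintf("mir%03d", seq_len(cfg$M))
  target_ids <- sprintf("tgt%04d", seq_len(cfg$N))
  mirna_seqs <- vapply(seq_len(cfg$M), function(i)
    plant_motif(rand_seq(cfg$seq_len_mirna), motifs[mb[i]], 1L,
                cfg$motif_strength), "")
  n_slots_t <- max(1L, cfg$seq_len_target %/% 30L)
  target_seqs <- vapply(seq_len(cfg$N), function(j)
    plant_motif(rand_seq(cfg$seq_len_target), motifs[tb[j]], n_slots_t,
                cfg$motif_strength), "")
  names(mirna_seqs) <- mirna_ids
  names(target_seqs) <- target_ids

  p <- matrix(cfg$p_out, cfg$M, cfg$N)
  p[outer(mb, tb, "==")] <- cfg$p_in
  A <- matrix(stats::rbinom(cfg$M * cfg$N, 1L, p), cfg$M, cfg$N,
              dimnames = list(mirna_ids, target_ids))
  pp <- positive_pairs(A)
  pairs <- data.frame(mirna = mirna_ids[pp[, 1]],
                      target = target_ids[pp[, 2]],
                      stringsAsFactors = FALSE)
  list(mirna_seqs = mirna_seqs, target_seqs = target_seqs,
       pairs = pairs, A = A,
       mirna_blocks = mb, target_blocks = tb, motifs = motifs,
       config = cfg)
}

#' Write a synthetic dataset bundle to disk
#'
#' Emits `mirna.fasta`, `target.fasta`, `pairs.tsv` and a `config.json`
#' provenance sidecar into `dir`.
#'
#' @param data Output of [synth_generate()].
#' @param dir Output directory (created if absent).
#' @export
write_synth_bundle <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(data$mirna_seqs, file.path(dir, "mirna.fasta"))
  write_fasta(data$target_seqs, file.path(dir, "target.fasta"))
  write_pairs(data$pairs, file.path(dir, "pairs.tsv"))
  jsonlite::write_json(unclass(data$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Degenerate edge-case fixtures for error-path testing
#'
#' Returns a named list of tiny datasets exercising the package's error
#' handling: a single known positive, sequence sets with no shared motifs,
#' an all-positive association matrix (which the training loss must reject:
#' the negative set is empty), and duplicated sequences (Jaccard similarity
#' exactly 1).
#'
#' @param seed Integer seed.
#' @return Named list of fixtures, each a list like [synth_generate()]'s
#'   output.
#' @export
degenerate_fixtures <- function(seed = 1L) {
  set.seed(seed)
  mk <- function(M, N, A) {
    ms <- vapply(seq_len(M), function(i) rand_seq(22L), "")
    ts <- vapply(seq_len(N), function(i) rand_seq(60L), "")
    names(ms) <- sprintf("mir%02d", seq_len(M))
    names(ts) <- sprintf("tgt%02d", seq_len(N))
    dimnames(A) <- list(names(ms), names(ts))
    list(mirna_seqs = ms, target_seqs = ts, A = A)
  }
  single <- mk(3, 4, {
    A <- matrix(0, 3, 4); A[2, 3] <- 1; A
  })
  all_pos <- mk(3, 4, matrix(1, 3, 4))
  dup <- mk(4, 4, matrix(rbinom(16, 1, 0.4), 4, 4))
  dup$mirna_seqs[2] <- dup$mirna_seqs[1]
  no_motif <- synth_generate(synth_config(M = 10L, N = 20L, n_blocks = 2L,
                                          motif_strength = 0, seed = seed))
  list(single_positive = single, all_positive = all_pos,
       duplicate_sequence = dup, no_motif = no_motif)
}
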