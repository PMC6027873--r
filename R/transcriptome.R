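#' Generate a random reference transcriptome
#'
#' Draws `n_transcripts` random transcript sequences over `{A,C,G,T}` with
#' lengths uniform in `length_range` and a target GC fraction, plus
#' log-normal expression weights. The transcriptome defines both the
#' molecules the simulator transcribes and the "bases sequenced"
#' denominators used for composition normalization downstream.
#'
#' @param n_transcripts Number of transcripts (>= 1).
#' @param length_range Integer pair, minimum and maximum transcript length
#'   (both >= 200).
#' @param gc_fraction Target GC content, strictly between 0 and 1. The
#'   realized GC of the whole transcriptome is binomially distributed around
#'   this value (within about 1 percentage point for >= 10 kb total).
#' @param weights Optional positive expression weights, one per transcript.
#'   Defaults to `rlnorm(n_transcripts)` draws.
#' @param seed Optional integer seed; the result is deterministic given the
#'   seed and parameters.
#'
#' @return A `transcriptome` tibble with columns `id`, `sequence`, `weight`.
#' @examples
#' tx <- generate_transcriptome(3, c(500, 600), 0.5, seed = 1)
#' nchar(tx$sequence)
#' @export
generate_transcriptome <- function(n_transcripts, length_range = c(800L, 1200L),
                                   gc_fraction = 0.5, weights = NULL, seed = NULL) {
  if (!is.numeric(n_transcripts) || length(n_transcripts) != 1L || n_transcripts < 1)
    stop_param("n_transcripts must be a single integer >= 1")
  if (length(length_range) != 2L || any(length_range < 200) ||
      length_range[2] < length_range[1])
    stop_param("length_range must be an increasing pair of lengths >= 200")
  if (!is.numeric(gc_fraction) || gc_fraction <= 0 || gc_fraction >= 1)
    stop_param("gc_fraction must lie strictly between 0 and 1")
  n_transcripts <- as.integer(n_transcripts)
  with_seed(seed, {
    lens <- sample_range(length_range[1], length_range[2], n_transcripts)
    probs <- c((1 - gc_fraction) / 2, gc_fraction / 2,
               gc_fraction / 2, (1 - gc_fraction) / 2)
    codes <- sample.int(4L, sum(lens), replace = TRUE, prob = probs)
    ends <- cumsum(lens)
    starts <- c(1L, head(ends, -1L) + 1L)
    seqs <- vapply(seq_len(n_transcripts), function(i)
      codes_to_dna(codes[starts[i]:ends[i]]), character(1))
    if (is.null(weights)) weights <- stats::rlnorm(n_transcripts)
    new_transcriptome(tibble::tibble(
      id = sprintf("tx%03d", seq_len(n_transcripts)),
      sequence = seqs,
      weight = weights
    ))
  })
}

#' Construct a transcriptome from an id/sequence/weight table
#'
#' @param df Data frame with columns `id`, `sequence`, `weight`.
#' @return A validated `transcriptome` tibble.
#' @export
new_transcriptome <- function(df) {
  validate_transcriptome(df)
  class(df) <- unique(c("transcriptome", class(df)))
  df
}

validate_transcriptome <- function(tx) {
  stopifnot(all(c("id", "sequence", "weight") %in% names(tx)))
  if (nrow(tx) < 1L) stop_param("transcriptome has no transcripts")
  if (any(nchar(tx$sequence) == 0L)) stop_param("empty transcript sequence")
  if (any(grepl("[^ACGT]", tx$sequence)))
    stop_param("transcript sequences must be over {A,C,G,T}")
  if (!all(tx$weight > 0) || sum(tx$weight) <= 0)
    stop_param("expression weights must be positive")
  if (anyDuplicated(tx$id)) stop_param("duplicate transcript ids")
  invisible(tx)
}

# list of integer code vectors, one per transcript (hot-path representation)
tx_codes <- function(tx) {
  lapply(tx$sequence, dna_to_codes)
}

#' Base composition of a transcriptome
#'
#' @param tx A `transcriptome`.
#' @param weight_by_coverage Optional named list of per-position coverage
#'   vectors (as produced by [call_errors()]); when supplied, each position
#'   contributes its sequencing depth rather than 1.
#' @return Named numeric vector of A/C/G/T counts.
#' @export
base_composition <- function(tx, weight_by_coverage = NULL) {
  codes <- tx_codes(tx)
  out <- numeric(4)
  for (i in seq_along(codes)) {
    if (is.null(weight_by_coverage)) {
      out <- out + tabulate(codes[[i]], 4L)
    } else {
      cov <- weight_by_coverage[[tx$id[i]]]
      if (is.null(cov)) next
      for (b in 1:4) out[b] <- out[b] + sum(cov[codes[[i]] == b])
    }
  }
  names(out) <- BASES
  out
}

#' Write / read a transcriptome as FASTA
#'
#' Sequences go through Biostrings; expression weights are not part of the
#' FASTA format and can be supplied on read (default: uniform).
#'
#' @param tx A `transcriptome`.
#' @param path FASTA file path.
#' @rdname transcriptome-io
#' @export
write_transcriptome_fasta <- function(tx, path) {
  x <- Biostrings::DNAStringSet(tx$sequence)
  names(x) <- tx$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @param weights Optional weights for `read_transcriptome_fasta`.
#' @rdname transcriptome-io
#' @export
read_transcriptome_fasta <- function(path, weights = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  new_transcriptome(tibble::tibble(
    id = names(x),
    sequence = unname(as.character(x)),
    weight = weights %||% rep(1, length(x))
  ))
}
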