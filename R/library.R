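# Rolling-circle library construction: shear molecules into 80-100 nt
# fragments, circularize each fragment with a random rotation, roll it out
# into a tandem concatemer, shear the concatemer to 300-450 bp and read the
# first 300 bases with per-copy sequencing miscalls.

#' Build a tandem-repeat sequencing library from molecules
#'
#' Emulates the circularized-cDNA library chemistry: each molecule is cut
#' into consecutive fragments with lengths uniform on `frag_len` (the final
#' short remainder is discarded, and molecules shorter than the minimum
#' fragment length are skipped and counted); each fragment is circularized
#' at a uniformly random rotation, rolled out head-to-tail, cut to a length
#' uniform on `shear_len` and read for its first `read_length` bases.
#' Sequencing and reverse-transcription miscalls are applied jointly, once
#' per base of the read (i.e. independently per repeat copy), at
#' `model$seq_error_rate`; qualities come from the model's quality ranges.
#'
#' @param ms A `molecule_set` from [simulate_molecules()].
#' @param model The [error_model()] supplying `seq_error_rate` and the
#'   quality model.
#' @param n_reads Optional cap: a uniform subsample of this many fragments
#'   becomes the library (all fragments if fewer).
#' @param seed Optional integer seed.
#' @param read_length Read length in bases (default 300).
#' @param frag_len Fragment length range (default 80-100 nt).
#' @param shear_len Concatemer shear length range (default 300-450 bp).
#' @param rotate Apply a uniformly random circularization rotation to each
#'   fragment (default TRUE, the library chemistry; FALSE is a diagnostic
#'   mode for oracle tests).
#'
#' @return A `repeat_reads` object: integer code matrix `seq` (n x
#'   read_length), Phred matrix `qual`, read `ids`, a hidden `provenance`
#'   tibble (source molecule, fragment bounds, rotation) used only by
#'   oracle tests, and the count of skipped short molecules.
#' @export
build_library <- function(ms, model, n_reads = NULL, seed = NULL,
                          read_length = 300L, frag_len = c(80L, 100L),
                          shear_len = c(300L, 450L), rotate = TRUE) {
  if (!inherits(ms, "molecule_set")) stop_param("ms must be a molecule_set")
  if (length(ms$molecules) == 0L) stop_param("no molecules to fragment")
  with_seed(seed, {
    lens <- vapply(ms$molecules, function(m) length(m$seq), integer(1))
    skipped <- sum(lens < frag_len[1])
    frag_mol <- integer(0); frag_start <- integer(0); frag_width <- integer(0)
    for (i in which(lens >= frag_len[1])) {
      len <- lens[i]
      k <- len %/% frag_len[1] + 1L
      fl <- sample_range(frag_len[1], frag_len[2], k)
      ends <- cumsum(fl)
      keep <- ends <= len
      if (!any(keep)) next
      fl <- fl[keep]; ends <- ends[keep]
      frag_mol <- c(frag_mol, rep(i, length(fl)))
      frag_start <- c(frag_start, ends - fl + 1L)
      frag_width <- c(frag_width, fl)
    }
    nf <- length(frag_mol)
    if (nf == 0L) stop_param("no fragments produced")
    if (!is.null(n_reads) && nf > n_reads) {
      sel <- sample.int(nf, n_reads)
      frag_mol <- frag_mol[sel]; frag_start <- frag_start[sel]
      frag_width <- frag_width[sel]
      nf <- n_reads
    }
    rot <- if (rotate) floor(stats::runif(nf) * frag_width) else rep(0L, nf)
    cut_len <- sample_range(shear_len[1], shear_len[2], nf)
    rl <- pmin(read_length, cut_len)

    M <- matrix(NA_integer_, nf, read_length)
    for (f in seq_len(nf)) {
      mol <- ms$molecules[[frag_mol[f]]]
      p <- frag_width[f]
      frag <- mol$seq[frag_start[f]:(frag_start[f] + p - 1L)]
      M[f, seq_len(rl[f])] <- frag[((rot[f] + 0:(rl[f] - 1L)) %% p) + 1L]
    }
    n_bases <- sum(rl)
    Q <- matrix(NA_integer_, nf, read_length)
    live <- !is.na(M)
    qc <- model$quality_correct; qe <- model$quality_error
    Q[live] <- sample_range(qc[1], qc[2], n_bases)
    n_err <- stats::rbinom(1L, n_bases, model$seq_error_rate)
    if (n_err > 0L) {
      cells <- which(live)[sample.int(n_bases, n_err)]
      M[cells] <- ((M[cells] - 1L + sample.int(3L, n_err, replace = TRUE)) %% 4L) + 1L
      Q[cells] <- sample_range(qe[1], qe[2], n_err)
    }
    prov <- tibble::tibble(
      read_id = sprintf("read%06d", seq_len(nf)),
      molecule = frag_mol,
      transcript_id = vapply(frag_mol, function(i)
        ms$molecules[[i]]$transcript_id, character(1)),
      frag_start = frag_start, frag_len = frag_width, rotation = rot,
      read_len = rl
    )
    structure(list(ids = prov$read_id, seq = M, qual = Q,
                   provenance = prov, skipped_molecules = skipped),
              class = "repeat_reads")
  })
}

#' @export
print.repeat_reads <- function(x, ...) {
  cat("<repeat_reads> ", nrow(x$seq), " reads x ", ncol(x$seq),
      " bases max\n", sep = "")
  if (x$skipped_molecules %||% 0L > 0L)
    cat("  (", x$skipped_molecules, " molecules shorter than the minimum",
        " fragment length were skipped)\n", sep = "")
  invisible(x)
}

#' Number of reads in a `repeat_reads` object
#' @param reads A `repeat_reads` object.
#' @return Integer count.
#' @export
n_reads <- function(reads) nrow(reads$seq)

#' Write / read repeat reads as FASTQ (Phred+33)
#'
#' IO goes through Biostrings. Reading back loses the simulator provenance,
#' exactly as for real data.
#'
#' @param reads A `repeat_reads` object.
#' @param path FASTQ file path.
#' @rdname fastq-io
#' @export
write_fastq <- function(reads, path) {
  n <- nrow(reads$seq)
  seqs <- character(n); quals <- character(n)
  for (i in seq_len(n)) {
    v <- reads$seq[i, ]
    keep <- !is.na(v)
    seqs[i] <- intToUtf8(c(65L, 67L, 71L, 84L)[v[keep]])
    quals[i] <- intToUtf8(reads$qual[i, keep] + 33L)
  }
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
  names(x) <- reads$ids
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' @rdname fastq-io
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping its own metadata columns on conversion
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  seqs <- as.character(x)
  quals <- as.character(Biostrings::quality(x))
  structure(list(
    ids = names(x) %||% sprintf("read%06d", seq_along(seqs)),
    seq = strings_to_code_matrix(seqs),
    qual = qual_strings_to_matrix(quals),
    provenance = NULL, skipped_molecules = 0L
  ), class = "repeat_reads")
}

# reference (0-based) position of each molecule base, resolving indel shifts
molecule_refpos <- function(mol) {
  mol$refpos %||% (seq_along(mol$seq) - 1L)
}
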