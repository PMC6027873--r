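# Programmatic fixtures: tiny transcriptomes and hand-built tandem-repeat
# reads with known fragment, rotation and qualities.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

tiny_tx <- function(seqs, weights = NULL) {
  seqs <- unlist(seqs)
  new_transcriptome(tibble::tibble(
    id = sprintf("t%02d", seq_along(seqs)),
    sequence = seqs,
    weight = weights %||% rep(1, length(seqs))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a repeat_reads object holding one read: `fragment` rotated by
# `rotation`, tiled to `read_length` bases, constant quality `q` unless a
# `qual` vector is given. `edits` is an optional list of
# list(offset =, base =, q =) applied after tiling (offset 1-based within
# the read), emulating per-copy sequencing miscalls.
fixture_read <- function(fragment, rotation = 0L, read_length = 300L,
                         q = 35L, qual = NULL, edits = list()) {
  f <- strsplit(fragment, "", fixed = TRUE)[[1]]
  codes <- match(f, c("A", "C", "G", "T"))
  p <- length(codes)
  idx <- ((rotation + 0:(read_length - 1L)) %% p) + 1L
  seqv <- codes[idx]
  qv <- if (is.null(qual)) rep(as.integer(q), read_length) else as.integer(qual)
  for (e in edits) {
    seqv[e$offset] <- match(e$base, c("A", "C", "G", "T"))
    if (!is.null(e$q)) qv[e$offset] <- as.integer(e$q)
  }
  structure(list(
    ids = "fix1",
    seq = matrix(seqv, nrow = 1),
    qual = matrix(qv, nrow = 1),
    provenance = NULL, skipped_molecules = 0L
  ), class = "repeat_reads")
}

# a molecule_set wrapping explicit sequences (no injected errors)
fixture_molecules <- function(seqs, transcript_ids = NULL) {
  mols <- lapply(seq_along(seqs), function(i) {
    codes <- match(strsplit(seqs[[i]], "", fixed = TRUE)[[1]],
                   c("A", "C", "G", "T"))
    list(id = i, transcript_id = (transcript_ids %||% rep("t01", length(seqs)))[i],
         seq = codes, refpos = NULL)
  })
  bc <- c(A = 0, C = 0, G = 0, T = 0)
  for (m in mols) bc <- bc + tabulate(m$seq, 4)
  structure(list(molecules = mols,
                 ledger = tibble::tibble(molecule_id = integer(0),
                                         transcript_id = character(0),
                                         position = integer(0),
                                         type = character(0),
                                         from_base = character(0),
                                         to_base = character(0)),
                 base_counts = bc),
            class = "molecule_set")
}

# default-sized study config scaled down for unit tests
tiny_config <- function(...) {
  args <- utils::modifyList(list(n_transcripts = 8L, reads_per_sample = 250L,
                                 mc_samples = 1e4), list(...))
  do.call(run_config, args)
}
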