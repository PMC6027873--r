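# Mapping consensus fragments back to the reference. Fragments are
# contiguous transcript windows read out from a circularized fragment, so a
# consensus is a *rotation* of its reference window: it aligns as at most
# two blocks that are adjacent in the reference. A 31-mer exact seed anchors
# one block; the junction (rotation point) is found by a cumulative-sum
# scan over the two candidate branch alignments; fragments that still align
# poorly are retried with a single-base gap (transcription indels) over
# every candidate junction; anything else is discarded and counted.
# Mismatches whose coordinate differs between equally-scoring junction
# placements are masked out of both events and denominator. The inner
# loops live in src/mapping.cpp.

STATUS_LABELS <- c("ok", "too_short", "unmapped", "ambiguous",
                   "discarded_indel")

#' Build an exact-seed index of a transcriptome
#'
#' Hashes every k-mer (default 31) of every transcript, plus a shorter
#' rescue tier (default 17) consulted only when no clean 31-mer window of a
#' fragment hits the index — which happens when masked positions, the
#' rotation junction and a genuine error between them break every long
#' window. Without the rescue tier, error-carrying fragments would be
#' preferentially unmappable and rates biased low. K-mers occurring at
#' several loci keep all of them, so ambiguous placements can be detected
#' and discarded.
#'
#' @param tx A `transcriptome`.
#' @param k Primary seed length (at most 31).
#' @param k_rescue Rescue seed length (0 disables the tier).
#' @return A `seed_index` object (valid within the current session).
#' @export
build_seed_index <- function(tx, k = 31L, k_rescue = 17L) {
  validate_transcriptome(tx)
  if (k > 31L || k < 1L) stop_param("seed length must be in 1..31")
  codes <- tx_codes(tx)
  ptr <- build_index_cpp(codes, as.integer(k), as.integer(k_rescue %||% 0L))
  structure(list(ptr = ptr, tx_id = tx$id, codes = codes,
                 k = as.integer(k), k_rescue = as.integer(k_rescue %||% 0L)),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat("<seed_index> ", length(x$tx_id), " transcripts, k = ", x$k,
      if (x$k_rescue > 0) paste0(" (+", x$k_rescue, " rescue)"), "\n",
      sep = "")
  invisible(x)
}

# run the C++ mapper over a list of consensus code vectors and fold the
# result into events + denominator accumulators
map_fragment_batch <- function(cons_list, index, max_mm = 7L,
                               min_called = 30L) {
  map_fragments_cpp(cons_list, index$ptr, as.integer(max_mm),
                    as.integer(min_called))
}

batch_events <- function(raw, frag_ids, tx) {
  obs <- rep(NA_character_, length(raw$ev_obs))
  ok <- !is.na(raw$ev_obs)
  obs[ok] <- BASES[raw$ev_obs[ok]]
  tibble::tibble(
    read_id = frag_ids[raw$ev_frag],
    transcript_id = tx$id[raw$ev_t],
    position = raw$ev_pos,
    ref = BASES[raw$ev_ref],
    type = c("sub", "ins", "del")[raw$ev_type + 1L],
    obs = obs
  )
}

batch_denominator <- function(raw, tx) {
  cov <- raw$coverage
  names(cov) <- tx$id
  structure(list(
    N = sum(raw$n_b),
    N_b = stats::setNames(raw$n_b, BASES),
    dinuc = matrix(raw$dinuc, 4, 4, dimnames = list(BASES, BASES)),
    coverage = cov
  ), class = "call_denominator")
}

#' @export
print.call_denominator <- function(x, ...) {
  cat("<call_denominator> N =", format(x$N, big.mark = ","), "called bases\n")
  print(x$N_b)
  invisible(x)
}

#' Map a consensus fragment and call candidate errors
#'
#' Aligns one consensus fragment to its unique best transcript window
#' (exact 31-mer seed, rotation-aware banded extension, single-base-gap
#' retry) and emits one `ErrorEvent` row per aligned mismatch or
#' single-base gap. Fragments whose best placement is tied between two or
#' more loci are discarded.
#'
#' @param cf A `consensus_fragment` from [build_consensus()], or a bare
#'   sequence string.
#' @param tx The reference `transcriptome`.
#' @param index Optional prebuilt [build_seed_index()] (rebuilt if NULL).
#' @param max_mm Maximum mismatches tolerated in an accepted alignment.
#' @return A tibble of error events (possibly empty) with columns
#'   `transcript_id`, `position` (0-based), `ref`, `type`, `obs`; the
#'   alignment status and the denominator contribution (`N`, per-base
#'   counts) are attached as attributes `status` and `denominator`.
#' @export
map_and_call <- function(cf, tx, index = NULL, max_mm = 7L) {
  if (nrow(tx) < 1L) stop_param("empty transcriptome")
  if (is.character(cf)) cf <- list(codes = dna_to_codes(cf))
  if (is.null(index)) index <- build_seed_index(tx)
  raw <- map_fragment_batch(list(as.integer(cf$codes)), index,
                            max_mm = max_mm)
  ev <- batch_events(raw, "single", tx)
  ev$read_id <- NULL
  attr(ev, "status") <- STATUS_LABELS[raw$status + 1L]
  attr(ev, "denominator") <- batch_denominator(raw, tx)
  ev
}

#' Call transcription errors from tandem-repeat reads
#'
#' The full read-level pipeline: period detection, quality-aware unanimity
#' consensus, rotation-aware mapping, and error-event emission, batched
#' over all reads. Positions that are masked, unaligned, or part of a
#' discarded fragment never enter the denominator.
#'
#' @param reads A `repeat_reads` object.
#' @param tx The reference `transcriptome`.
#' @param q_cutoff Quality cutoff for repeat-copy bases (default 20).
#' @param min_repeats Minimum qualifying repeat copies (default 3).
#' @param mode Consensus mode, `"unanimity"` (default) or `"majority"`.
#' @param index Optional prebuilt seed index (saves time across samples).
#' @param max_mm Maximum mismatches per accepted fragment alignment.
#'
#' @return An `error_calls` list: `events` (tibble as in [map_and_call()],
#'   plus `read_id`), `denominator` (`N`, `N_b`, dinucleotide counts and
#'   per-transcript coverage), and `counts` — reads dropped at each stage
#'   (`no_period`, `too_few_repeats`, `too_short`, `unmapped`, `ambiguous`,
#'   `discarded_indel`, and `n_used`).
#' @export
call_errors <- function(reads, tx, q_cutoff = 20L, min_repeats = 3L,
                        mode = "unanimity", index = NULL, max_mm = 7L) {
  validate_transcriptome(tx)
  if (is.null(index)) index <- build_seed_index(tx)
  M <- reads$seq; Q <- reads$qual
  periods <- detect_periods_matrix(M)
  counts <- c(no_period = sum(is.na(periods)), too_few_repeats = 0L,
              too_short = 0L, unmapped = 0L, ambiguous = 0L,
              discarded_indel = 0L, n_used = 0L)
  cons_list <- list()
  frag_ids <- character(0)
  for (p in sort(unique(periods[!is.na(periods)]))) {
    rows <- which(!is.na(periods) & periods == p)
    cb <- consensus_matrix(M[rows, , drop = FALSE], Q[rows, , drop = FALSE],
                           p, q_cutoff, min_repeats, mode)
    counts["too_few_repeats"] <- counts["too_few_repeats"] + sum(!cb$ok)
    keep <- which(cb$ok)
    if (length(keep) == 0L) next
    cons_list <- c(cons_list, lapply(keep, function(ri) cb$cons[ri, ]))
    frag_ids <- c(frag_ids, reads$ids[rows[keep]])
  }
  if (length(cons_list) == 0L) {
    raw <- map_fragment_batch(list(), index, max_mm)
  } else {
    raw <- map_fragment_batch(cons_list, index, max_mm)
  }
  st <- table(factor(STATUS_LABELS[raw$status + 1L],
                     levels = STATUS_LABELS))
  counts["too_short"] <- counts["too_short"] + st[["too_short"]]
  counts["unmapped"] <- counts["unmapped"] + st[["unmapped"]]
  counts["ambiguous"] <- counts["ambiguous"] + st[["ambiguous"]]
  counts["discarded_indel"] <- counts["discarded_indel"] +
    st[["discarded_indel"]]
  counts["n_used"] <- counts["n_used"] + st[["ok"]]
  structure(list(
    events = batch_events(raw, frag_ids, tx),
    denominator = batch_denominator(raw, tx),
    counts = counts
  ), class = "error_calls")
}

#' @export
print.error_calls <- function(x, ...) {
  cat("<error_calls> ", nrow(x$events), " events over ",
      format(x$denominator$N, big.mark = ","), " called bases (",
      x$counts["n_used"], " fragments used)\n", sep = "")
  invisible(x)
}
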