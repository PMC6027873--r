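# RNA:DNA-hybrid context analysis. During elongation the ~9 most recently
# transcribed bases stay paired with the template inside the polymerase, so
# the reference bases at positions -1..-9 upstream (5') of an error site
# reconstruct the hybrid that held the erroneous 3' end. Composition at
# those positions is compared between strain groups and normalized against
# a Monte Carlo background drawn from the sequenced transcriptome.

#' Upstream (RNA:DNA hybrid) context of error events
#'
#' Returns the reference bases at positions -1..-depth relative to each
#' event (position -1 first, i.e. most recently transcribed base first),
#' truncated at the transcript start.
#'
#' @param events Event tibble with `transcript_id` and 0-based `position`.
#' @param tx The reference `transcriptome`.
#' @param depth How many upstream bases (default 9, the hybrid length).
#' @return Character vector of contexts, one per event.
#' @examples
#' tx <- new_transcriptome(tibble::tibble(id = "t", sequence = "CCCCCCCCCG",
#'                                        weight = 1))
#' ev <- tibble::tibble(transcript_id = "t", position = 9L)
#' upstream_context(ev, tx)
#' @export
upstream_context <- function(events, tx, depth = 9L) {
  idx <- match(events$transcript_id, tx$id)
  if (anyNA(idx)) stop_param("event transcript not in transcriptome")
  vapply(seq_len(nrow(events)), function(i) {
    pos <- events$position[i] # 0-based
    lo <- max(0L, pos - depth)
    if (pos == 0L) return("")
    s <- substr(tx$sequence[idx[i]], lo + 1L, pos)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1))
}

# integer matrix depth x n_events of upstream base codes (NA past start)
upstream_codes <- function(events, tx, depth = 9L) {
  codes <- tx_codes(tx)
  idx <- match(events$transcript_id, tx$id)
  out <- matrix(NA_integer_, depth, nrow(events))
  for (i in seq_len(nrow(events))) {
    pos <- events$position[i]
    d <- seq_len(min(depth, pos))
    if (length(d) > 0) out[d, i] <- codes[[idx[i]]][pos + 1L - d]
  }
  out
}

#' Monte Carlo background composition of the sequenced transcriptome
#'
#' For each focal base identity, samples `n_samples` sequenced positions of
#' that identity (uniformly with replacement, weighted by per-position
#' sequencing depth) and tallies the base composition at positions
#' -1..-depth upstream. This is the null composition against which hybrid
#' contexts of actual errors are normalized.
#'
#' @param tx The reference `transcriptome`.
#' @param coverage Optional named list of per-position depth vectors (as in
#'   an `error_calls` denominator); NULL means uniform depth 1.
#' @param n_samples Draws per focal base (default 1e6).
#' @param depth Upstream window (default 9).
#' @param seed Optional integer seed.
#' @param focal Focal base identities to sample (default all four); a
#'   requested focal base absent from the sequenced transcriptome is an
#'   error.
#' @return A `context_background`: list with `prop` and `count` arrays of
#'   dimension `[focal base, position, base]`, and `n_valid` (draws with at
#'   least `|position|` upstream bases) of dimension `[focal, position]`.
#' @export
background_composition <- function(tx, coverage = NULL, n_samples = 1e6,
                                   depth = 9L, seed = NULL, focal = BASES) {
  validate_transcriptome(tx)
  codes <- tx_codes(tx)
  lens <- lengths(codes)
  flat <- unlist(codes)
  local_pos <- unlist(lapply(lens, seq_len))
  cov <- if (is.null(coverage)) rep(1, length(flat))
         else unlist(coverage[tx$id])
  if (length(cov) != length(flat))
    stop_param("coverage does not match the transcriptome")
  dn <- list(focal = BASES, position = paste0("-", seq_len(depth)), base = BASES)
  count <- array(0, dim = c(4, depth, 4), dimnames = dn)
  n_valid <- matrix(0, 4, depth, dimnames = dn[1:2])
  with_seed(seed, {
    for (f in match(focal, BASES)) {
      pool <- which(flat == f & cov > 0)
      if (length(pool) == 0L)
        stop_param("focal base ", BASES[f], " absent from the sequenced ",
                   "transcriptome")
      draw <- pool[sample.int(length(pool), n_samples, replace = TRUE,
                              prob = cov[pool])]
      for (d in seq_len(depth)) {
        valid <- local_pos[draw] > d
        up <- flat[draw[valid] - d]
        count[f, d, ] <- tabulate(up, 4L)
        n_valid[f, d] <- sum(valid)
      }
    }
  })
  prop <- count / pmax(array(n_valid, dim = c(4, depth, 4)), 1)
  structure(list(prop = prop, count = count, n_valid = n_valid,
                 n_samples = n_samples, depth = depth),
            class = "context_background")
}

#' Hybrid-composition enrichment between two groups of errors
#'
#' For each upstream position -1..-depth and each base, builds the 2x2
#' table (occurrences of that base versus any other base at that position,
#' group 1 versus group 2), tests it with a two-sided Fisher's exact test,
#' and corrects the full position-by-base grid with Benjamini-Hochberg.
#' Composition proportions are also reported after dividing by the Monte
#' Carlo background (mixed over each group's focal-base spectrum) and
#' rescaling to sum to one per position, which removes the transcriptome's
#' own composition signal: under a uniform background the normalized
#' proportions equal the raw ones.
#'
#' With `mode = "group_vs_background"` the second group is replaced by the
#' Monte Carlo draws themselves, testing each group's composition directly
#' against the sequenced-transcriptome null.
#'
#' @param events_1,events_2 Event tibbles for the two groups (e.g. all
#'   errors from greA-intact and greA-deleted samples). `events_2` is
#'   ignored for `mode = "group_vs_background"`.
#' @param tx The reference `transcriptome`.
#' @param background A [background_composition()] result.
#' @param labels Group labels of length 2.
#' @param depth Upstream window (default 9).
#' @param fdr Benjamini-Hochberg false discovery rate (default 0.05).
#' @param mode Comparison mode; `"group_vs_group"` is the default.
#' @return A `context_enrichment` list: `profile` (tidy tibble of counts,
#'   proportions, background and normalized proportions per group x
#'   position x base) and `tests` (position x base Fisher p, BH q,
#'   rejection flags).
#' @export
composition_enrichment <- function(events_1, events_2 = NULL, tx, background,
                                   labels = c("group1", "group2"),
                                   depth = 9L, fdr = 0.05,
                                   mode = c("group_vs_group",
                                            "group_vs_background")) {
  mode <- match.arg(mode)
  if (nrow(events_1) == 0L) stop_param("group 1 has no errors")
  if (mode == "group_vs_group" && (is.null(events_2) || nrow(events_2) == 0L))
    stop_param("group 2 has no errors")
  count_grid <- function(ev) {
    up <- upstream_codes(ev, tx, depth)
    cnt <- matrix(0, depth, 4, dimnames = list(paste0("-", seq_len(depth)),
                                               BASES))
    for (d in seq_len(depth)) cnt[d, ] <- tabulate(up[d, ], 4L)
    cnt
  }
  mix_background <- function(ev) {
    # background mixed over the group's focal (reference) base spectrum
    w <- tabulate(match(ev$ref, BASES), 4L)
    w <- w / sum(w)
    bg <- matrix(0, depth, 4, dimnames = list(paste0("-", seq_len(depth)),
                                              BASES))
    for (f in 1:4) bg <- bg + w[f] * background$prop[f, seq_len(depth), ]
    bg
  }
  cnt1 <- count_grid(events_1)
  bg1 <- mix_background(events_1)
  if (mode == "group_vs_group") {
    cnt2 <- count_grid(events_2)
    bg2 <- mix_background(events_2)
  } else {
    # Monte Carlo draws as the comparison column, mixed like group 1
    w <- tabulate(match(events_1$ref, BASES), 4L)
    w <- w / sum(w)
    cnt2 <- matrix(0, depth, 4)
    for (f in 1:4)
      cnt2 <- cnt2 + w[f] * background$count[f, seq_len(depth), ]
    cnt2 <- round(cnt2)
    bg2 <- bg1
    labels[2] <- "background"
  }
  tot1 <- rowSums(cnt1); tot2 <- rowSums(cnt2)
  tests <- tidyr::expand_grid(position = -(seq_len(depth)), base = BASES)
  tests$p <- vapply(seq_len(nrow(tests)), function(i) {
    d <- -tests$position[i]; b <- match(tests$base[i], BASES)
    fisher_exact_2x2(matrix(c(cnt1[d, b], tot1[d] - cnt1[d, b],
                              cnt2[d, b], tot2[d] - cnt2[d, b]), 2,
                            byrow = TRUE))
  }, numeric(1))
  bh <- benjamini_hochberg(tests$p, fdr = fdr)
  tests$q <- bh$q
  tests$rejected <- bh$reject
  prof <- function(lab, cnt, tot, bg) {
    g <- tidyr::expand_grid(position = -(seq_len(depth)), base = BASES)
    g$group <- lab
    g$count <- vapply(seq_len(nrow(g)), function(i)
      cnt[-g$position[i], match(g$base[i], BASES)], numeric(1))
    g$total <- tot[-g$position]
    g$prop <- ifelse(g$total > 0, g$count / g$total, NA)
    g$background <- vapply(seq_len(nrow(g)), function(i)
      bg[-g$position[i], match(g$base[i], BASES)], numeric(1))
    # divide out the background, then rescale to proportions per position
    ratio <- g$prop / g$background
    g$norm_prop <- ratio / stats::ave(ratio, g$position, FUN = function(v)
      sum(v, na.rm = TRUE))
    g[, c("group", "position", "base", "count", "total", "prop",
          "background", "norm_prop")]
  }
  profile <- dplyr::bind_rows(prof(labels[1], cnt1, tot1, bg1),
                              prof(labels[2], cnt2, tot2, bg2))
  structure(list(profile = profile, tests = tests, mode = mode, fdr = fdr),
            class = "context_enrichment")
}

#' Per-type error rates conditioned on the preceding nucleotide
#'
#' For each substitution type X>Y and preceding base b, divides the count
#' of X>Y errors whose -1 reference base is b by the sequenced count of
#' (b, X) dinucleotides.
#'
#' @param events Event tibble (substitutions are used).
#' @param dinuc 4x4 sequenced dinucleotide count matrix
#'   (rows = preceding base, cols = focal base), from an `error_calls`
#'   denominator.
#' @param tx The reference `transcriptome`.
#' @param sample_id Optional sample label.
#' @return Tibble with `sample_id`, `preceding`, `type`, `count`, `denom`,
#'   `rate` (48 rows).
#' @export
per_type_context_rates <- function(events, dinuc, tx,
                                   sample_id = NA_character_) {
  subs <- events[events$type == "sub" & events$position > 0, , drop = FALSE]
  up <- if (nrow(subs) > 0) upstream_codes(subs, tx, depth = 1L)[1, ]
        else integer(0)
  grid <- tidyr::expand_grid(preceding = BASES, type = sub_types())
  grid$sample_id <- sample_id
  grid$count <- vapply(seq_len(nrow(grid)), function(i) {
    ft <- sub_type_codes(grid$type[i])
    sum(up == match(grid$preceding[i], BASES) &
          subs$ref == BASES[ft[1]] & subs$obs == BASES[ft[2]], na.rm = TRUE)
  }, numeric(1))
  grid$denom <- vapply(seq_len(nrow(grid)), function(i) {
    ft <- sub_type_codes(grid$type[i])
    dinuc[match(grid$preceding[i], BASES), ft[1]]
  }, numeric(1))
  if (any(grid$denom == 0 & grid$count > 0))
    stop_param("nonzero context error count over a zero dinucleotide ",
               "denominator")
  grid$rate <- ifelse(grid$denom > 0, grid$count / grid$denom, 0)
  grid[, c("sample_id", "preceding", "type", "count", "denom", "rate")]
}

#' Group comparison of preceding-nucleotide rates
#'
#' For each of the 48 (preceding base, substitution type) cells, compares
#' the per-sample conditional rates between gene-intact and gene-deleted
#' sample groups with the exact Mann-Whitney U test, Benjamini-Hochberg
#' corrected across the full 4x12 grid.
#'
#' @param context_rates Row-bound [per_type_context_rates()] tibbles for
#'   all samples.
#' @param design A [study_design()] tibble.
#' @param gene Grouping gene (`"greA"`, `"greB"` or `"dksA"`).
#' @param fdr False discovery rate (default 0.05).
#' @return Tibble with one row per (preceding, type): group means, U, p, q
#'   and the rejection flag.
#' @export
context_rate_tests <- function(context_rates, design, gene = "greA",
                               fdr = 0.05) {
  if (!gene %in% c("greA", "greB", "dksA")) stop_param("unknown gene ", gene)
  merged <- dplyr::left_join(context_rates, design, by = "sample_id")
  grid <- tidyr::expand_grid(preceding = BASES, type = sub_types())
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- merged[merged$preceding == grid$preceding[i] &
                     merged$type == grid$type[i], ]
    x <- cell$rate[cell[[gene]]]       # gene intact
    y <- cell$rate[!cell[[gene]]]      # gene deleted
    mw <- mann_whitney_exact(x, y)
    tibble::tibble(preceding = grid$preceding[i], type = grid$type[i],
                   mean_plus = mean(x), mean_minus = mean(y),
                   U = mw$U, p = mw$p.value)
  })
  out <- dplyr::bind_rows(res)
  bh <- benjamini_hochberg(out$p, fdr = fdr)
  out$q <- bh$q
  out$rejected <- bh$reject
  out
}
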