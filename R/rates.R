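# Error-rate tables. All per-type rates share one denominator N (the total
# number of called bases), so the twelve substitution rates plus the indel
# rates sum to the overall rate exactly; composition-normalized rates
# divide each type's count by the number of sequenced bases of its
# from-base identity instead.

#' Overall transcription error rate
#'
#' Total called errors divided by total bases sequenced.
#'
#' @param events Event tibble (as from [call_errors()]).
#' @param N Total called (denominator) bases.
#' @return A single rate.
#' @export
overall_rate <- function(events, N) {
  if (length(N) != 1L || is.na(N) || N <= 0)
    stop_param("undefined rate: N must be positive")
  nrow(events) / N
}

#' Per-type error rates for one sample
#'
#' Counts the twelve substitution types plus single-base insertions and
#' deletions, and reports each on two denominators: the total bases
#' sequenced `N` (columns `R_*`; these sum to the overall rate exactly)
#' and, for substitutions, the sequenced count of the from-base
#' (columns `Rn_*`, the composition-normalized rates used when comparing
#' across types).
#'
#' @param events Event tibble with columns `ref`, `obs`, `type`.
#' @param N Total called bases.
#' @param N_b Named numeric vector: called bases of identity A/C/G/T.
#' @param sample_id Optional sample label.
#' @return A one-row `rate_table` tibble.
#' @examples
#' ev <- tibble::tibble(ref = "G", obs = "A", type = "sub")
#' rt <- per_type_rates(ev, N = 1e6, N_b = c(A=3e5, C=2e5, G=2e5, T=3e5))
#' rt$Rn_GA
#' @export
per_type_rates <- function(events, N, N_b, sample_id = NA_character_) {
  if (length(N) != 1L || is.na(N) || N <= 0)
    stop_param("undefined rate: N must be positive")
  if (!all(BASES %in% names(N_b))) stop_param("N_b must be named A/C/G/T")
  N_b <- N_b[BASES]
  subs <- events[events$type == "sub", , drop = FALSE]
  types <- sub_types()
  keys <- paste0(subs$ref, ">", subs$obs)
  E_xy <- stats::setNames(as.numeric(table(factor(keys, levels = types))), types)
  E_ins <- sum(events$type == "ins")
  E_del <- sum(events$type == "del")
  E <- nrow(events)
  stopifnot(sum(E_xy) + E_ins + E_del == E) # exact conservation on counts
  from <- substr(types, 1L, 1L)
  if (any(N_b[from] == 0 & E_xy > 0))
    stop_param("undefined normalized rate: errors observed for a base with ",
               "zero sequenced count")
  out <- tibble::tibble(sample_id = sample_id, N = N, E = E,
                        R = E / N, E_ins = E_ins, E_del = E_del,
                        R_ins = E_ins / N, R_del = E_del / N)
  for (b in BASES) out[[paste0("N_", b)]] <- N_b[[b]]
  for (i in seq_along(types)) {
    key <- sub(">", "", types[i], fixed = TRUE)
    out[[paste0("E_", key)]] <- E_xy[[i]]
    out[[paste0("R_", key)]] <- E_xy[[i]] / N
    out[[paste0("Rn_", key)]] <- if (N_b[[from[i]]] > 0)
      E_xy[[i]] / N_b[[from[i]]] else 0
  }
  class(out) <- unique(c("rate_table", class(out)))
  out
}

#' Rate table for an `error_calls` result
#'
#' Convenience wrapper: [per_type_rates()] on the events and denominator of
#' one sample's [call_errors()] output.
#'
#' @param calls An `error_calls` object.
#' @param sample_id Optional sample label.
#' @return A one-row `rate_table` tibble.
#' @export
rate_table <- function(calls, sample_id = NA_character_) {
  per_type_rates(calls$events, calls$denominator$N, calls$denominator$N_b,
                 sample_id = sample_id)
}

#' Long-format rates for plotting
#'
#' @param rt A `rate_table` (one or more rows).
#' @return Tibble with `sample_id`, `type` (twelve substitution types plus
#'   `ins`/`del`), `count`, `rate`, and `rate_norm` (NA for indels).
#' @export
rates_long <- function(rt) {
  types <- sub_types()
  rows <- lapply(seq_len(nrow(rt)), function(i) {
    r <- rt[i, ]
    key <- sub(">", "", types, fixed = TRUE)
    tibble::tibble(
      sample_id = r$sample_id,
      type = c(types, "ins", "del"),
      count = c(as.numeric(r[paste0("E_", key)]), r$E_ins, r$E_del),
      rate = c(as.numeric(r[paste0("R_", key)]), r$R_ins, r$R_del),
      rate_norm = c(as.numeric(r[paste0("Rn_", key)]), NA, NA)
    )
  })
  dplyr::bind_rows(rows)
}

# per-transcript denominator (N_b by transcript) from coverage vectors
denominator_by_transcript <- function(denom, tx) {
  codes <- tx_codes(tx)
  out <- matrix(0, nrow(tx), 4, dimnames = list(tx$id, BASES))
  for (i in seq_len(nrow(tx))) {
    cov <- denom$coverage[[i]]
    for (b in 1:4) out[i, b] <- sum(cov[codes[[i]] == b])
  }
  out
}

#' Rates within strata of the transcriptome
#'
#' Computes a separate rate table inside each stratum (for example
#' expression-level tertiles or genomic location classes), using
#' stratum-specific denominators derived from the per-transcript coverage.
#' Strata with no sequenced bases are omitted with a warning.
#'
#' @param calls An `error_calls` object.
#' @param tx The reference `transcriptome`.
#' @param strata Named character vector: stratum label per transcript id.
#' @return A `rate_table` tibble with one row per stratum and a `stratum`
#'   column.
#' @export
stratify_rates <- function(calls, tx, strata) {
  if (!all(tx$id %in% names(strata)))
    stop_param("every transcript needs a stratum label")
  per_tx <- denominator_by_transcript(calls$denominator, tx)
  out <- list()
  for (s in unique(strata[tx$id])) {
    ids <- tx$id[strata[tx$id] == s]
    N_b <- colSums(per_tx[ids, , drop = FALSE])
    if (sum(N_b) == 0) {
      warning("stratum '", s, "' has no sequenced bases; omitted")
      next
    }
    ev <- calls$events[calls$events$transcript_id %in% ids, , drop = FALSE]
    rt <- per_type_rates(ev, sum(N_b), N_b, sample_id = s)
    rt$stratum <- s
    out[[s]] <- rt
  }
  dplyr::bind_rows(out)
}
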