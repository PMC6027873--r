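#' Specify a per-molecule transcription and sequencing error model
#'
#' The model has three layers. (1) Transcription errors injected once per
#' molecule: twelve per-base substitution rates indexed by (from, to), plus
#' single-base insertion and deletion rates, optionally modulated by the
#' identity of the preceding (5') base via `context_multipliers`. These are
#' the errors the consensus caller is supposed to recover, because they are
#' present in every tandem repeat of a fragment. (2) Sequencing (plus
#' reverse-transcription) miscalls applied once per repeat copy at
#' `seq_error_rate`. (3) A Phred quality model: correct calls draw qualities
#' uniformly from `quality_correct`, erroneous calls from `quality_error`.
#' The error range deliberately straddles Q20 so that some artifacts pass
#' the quality cutoff and must be removed by repeat concordance alone.
#'
#' @param sub_rates Either a 4x4 numeric matrix (rows = from, cols = to,
#'   dimnames A/C/G/T, diagonal ignored) or a named vector like
#'   `c("G>A" = 1e-4, ...)`; unnamed types default to 0. All rates must lie
#'   in `[0, 0.1]`.
#' @param ins_rate,del_rate Per-base single-nucleotide indel rates.
#' @param context_multipliers Optional multipliers on substitution rates by
#'   preceding base: a named vector like `c("C:G>A" = 5)` (preceding base,
#'   colon, substitution type) or a 4x4x4 array `[preceding, from, to]`.
#'   Default 1 everywhere.
#' @param seq_error_rate Per-base, per-repeat-copy miscall rate.
#' @param quality_correct,quality_error Integer ranges (inclusive) for Phred
#'   scores of correct and erroneous calls.
#'
#' @return An `error_model` object.
#' @examples
#' m <- error_model(c("G>A" = 1e-4), seq_error_rate = 0.01)
#' m$sub["G", "A"]
#' @export
error_model <- function(sub_rates = NULL, ins_rate = 0, del_rate = 0,
                        context_multipliers = NULL, seq_error_rate = 0,
                        quality_correct = c(30L, 40L),
                        quality_error = c(10L, 35L)) {
  sub <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  if (!is.null(sub_rates)) {
    if (is.matrix(sub_rates)) {
      stopifnot(all(dim(sub_rates) == c(4, 4)))
      sub[] <- sub_rates
    } else {
      if (is.null(names(sub_rates)) || !all(names(sub_rates) %in% sub_types()))
        stop_param("sub_rates vector must be named with types like \"G>A\"")
      for (nm in names(sub_rates)) {
        ft <- sub_type_codes(nm)
        sub[ft[1], ft[2]] <- sub_rates[[nm]]
      }
    }
  }
  diag(sub) <- 0
  mult <- array(1, dim = c(4, 4, 4), dimnames = list(BASES, BASES, BASES))
  if (!is.null(context_multipliers)) {
    if (is.array(context_multipliers) && length(dim(context_multipliers)) == 3) {
      stopifnot(all(dim(context_multipliers) == c(4, 4, 4)))
      mult[] <- context_multipliers
    } else {
      nms <- names(context_multipliers)
      if (is.null(nms) || !all(grepl("^[ACGT]:[ACGT]>[ACGT]$", nms)))
        stop_param("context_multipliers must be named like \"C:G>A\"")
      for (nm in nms) {
        prev <- match(substr(nm, 1, 1), BASES)
        ft <- sub_type_codes(substr(nm, 3, 5))
        mult[prev, ft[1], ft[2]] <- context_multipliers[[nm]]
      }
    }
  }
  rates <- c(sub[row(sub) != col(sub)], ins_rate, del_rate, seq_error_rate)
  if (any(!is.finite(rates)) || any(rates < 0) ||
      any(c(sub[row(sub) != col(sub)], ins_rate, del_rate) > 0.1))
    stop_param("all error rates must lie in [0, 0.1]")
  if (seq_error_rate > 0.5) stop_param("seq_error_rate too large")
  if (any(mult <= 0)) stop_param("context multipliers must be positive")
  structure(list(
    sub = sub, ins_rate = ins_rate, del_rate = del_rate, mult = mult,
    seq_error_rate = seq_error_rate,
    quality_correct = as.integer(quality_correct),
    quality_error = as.integer(quality_error)
  ), class = "error_model")
}

#' Default study error model
#'
#' A twelve-type substitution matrix spanning 2e-5 to 2e-4 per base
#' (transitions high, transversions low), single-base indels at 2e-5, and a
#' 1% per-copy sequencing miscall rate. `ga_multiplier` scales the G>A rate
#' and is how fidelity-factor-deletion genotypes are modeled.
#'
#' @param ga_multiplier Multiplier on the G>A substitution rate.
#' @param context_multipliers Passed through to [error_model()].
#' @param seq_error_rate Per-copy miscall rate.
#' @return An `error_model`.
#' @export
default_error_model <- function(ga_multiplier = 1, context_multipliers = NULL,
                                seq_error_rate = 0.01) {
  base <- c(
    "A>C" = 2e-5, "A>G" = 8e-5, "A>T" = 3e-5,
    "C>A" = 4e-5, "C>G" = 2e-5, "C>T" = 2e-4,
    "G>A" = 1e-4, "G>C" = 3e-5, "G>T" = 5e-5,
    "T>A" = 3e-5, "T>C" = 1.2e-4, "T>G" = 4e-5
  )
  base["G>A"] <- base["G>A"] * ga_multiplier
  error_model(base, ins_rate = 2e-5, del_rate = 2e-5,
              context_multipliers = context_multipliers,
              seq_error_rate = seq_error_rate)
}

#' @export
print.error_model <- function(x, ...) {
  cat("<error_model>\n  substitution rates (per base):\n")
  print(signif(x$sub, 3))
  cat("  ins:", x$ins_rate, " del:", x$del_rate,
      " seq_error:", x$seq_error_rate, "\n")
  if (any(x$mult != 1)) {
    idx <- which(x$mult != 1, arr.ind = TRUE)
    for (r in seq_len(nrow(idx)))
      cat(sprintf("  context %s:%s>%s x%g\n", BASES[idx[r, 1]],
                  BASES[idx[r, 2]], BASES[idx[r, 3]],
                  x$mult[idx[r, 1], idx[r, 2], idx[r, 3]]))
  }
  invisible(x)
}

#' Factorial fidelity-factor study design
#'
#' All eight combinations of greA/greB/dksA presence (the 2^3 factorial of
#' gene deletions), each with `replicates` independent samples. Grouping by
#' any one gene splits the design into two halves of four genotypes each.
#'
#' @param replicates Biological replicates per genotype (default 2).
#' @return A tibble with columns `sample_id`, `genotype`, `greA`, `greB`,
#'   `dksA` (logical: TRUE = gene intact), `replicate`.
#' @examples
#' d <- study_design()
#' table(d$greA)
#' @export
study_design <- function(replicates = 2L) {
  if (replicates < 1) stop_param("replicates must be >= 1")
  g <- expand.grid(dksA = c(TRUE, FALSE), greB = c(TRUE, FALSE),
                   greA = c(TRUE, FALSE))
  g <- g[, c("greA", "greB", "dksA")]
  genotype <- apply(g, 1, function(r) {
    del <- c("greA", "greB", "dksA")[!r]
    if (length(del) == 0) "WT" else paste0("d", paste(del, collapse = ""))
  })
  out <- do.call(rbind, lapply(seq_len(replicates), function(rep) {
    cbind(g, genotype = genotype, replicate = rep)
  }))
  out$sample_id <- paste0(out$genotype, "_r", out$replicate)
  tibble::as_tibble(out[, c("sample_id", "genotype", "greA", "greB",
                            "dksA", "replicate")])
}
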