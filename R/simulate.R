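#' Transcribe molecules with injected errors
#'
#' Draws `n_molecules` mRNA molecules from the transcriptome (transcripts
#' chosen proportional to expression weight) and mutates each base
#' independently: a base of identity `f` preceded by `p` becomes `t` with
#' probability `sub[f,t] * mult[p,f,t]`, is deleted with `del_rate`, or
#' gains an inserted base immediately 5' of it with `ins_rate`. Every
#' injected event is recorded in the truth ledger with its 0-based
#' transcript coordinate, the ground truth for parameter-recovery tests.
#'
#' @param tx A `transcriptome`.
#' @param n_molecules Number of molecules (>= 1).
#' @param model An [error_model()].
#' @param seed Optional integer seed.
#'
#' @return A `molecule_set`: list with `molecules` (each a list holding
#'   `id`, `transcript_id`, integer-coded `seq`, and `refpos`, the 0-based
#'   reference position of every molecule base, NA for inserted bases),
#'   `ledger` (tibble: `molecule_id`, `transcript_id`, `position`, `type`
#'   in `sub`/`ins`/`del`, `from_base`, `to_base`), and `base_counts`
#'   (total simulated template bases per identity).
#' @export
simulate_molecules <- function(tx, n_molecules, model, seed = NULL) {
  validate_transcriptome(tx)
  if (!inherits(model, "error_model")) stop_param("model must be an error_model")
  if (n_molecules < 1) stop_param("n_molecules must be >= 1")
  n_molecules <- as.integer(n_molecules)
  codes <- tx_codes(tx)

  # per-(preceding, from) total substitution rate; row 1 = no preceding base
  subtot <- matrix(0, 5, 4)
  for (f in 1:4) {
    subtot[1, f] <- sum(model$sub[f, ])
    for (p in 1:4) subtot[p + 1, f] <- sum(model$sub[f, ] * model$mult[p, f, ])
  }
  if (max(subtot) + model$ins_rate + model$del_rate > 0.5)
    stop_param("effective per-base total error rate exceeds 0.5")

  with_seed(seed, {
    pick <- sample.int(nrow(tx), n_molecules, replace = TRUE, prob = tx$weight)
    molecules <- vector("list", n_molecules)
    led_mol <- integer(0); led_tx <- character(0); led_pos <- integer(0)
    led_type <- character(0); led_from <- integer(0); led_to <- integer(0)
    base_counts <- numeric(4)

    for (t in seq_len(nrow(tx))) {
      mols_t <- which(pick == t)
      m <- length(mols_t)
      if (m == 0L) next
      tmpl <- codes[[t]]
      len <- length(tmpl)
      base_counts <- base_counts + tabulate(tmpl, 4L) * m
      prev <- c(0L, tmpl[-len])
      r <- subtot[cbind(prev + 1L, tmpl)] + model$ins_rate + model$del_rate
      # one uniform draw per (molecule, base); r recycles column-wise
      hit <- which(stats::runif(len * m) < r)
      pos <- (hit - 1L) %% len + 1L
      mol_of <- mols_t[(hit - 1L) %/% len + 1L]
      # resolve each hit into a concrete event
      ev <- vector("list", length(hit))
      for (h in seq_along(hit)) {
        f <- tmpl[pos[h]]
        p <- prev[pos[h]]
        pr_sub <- model$sub[f, ] * (if (p > 0L) model$mult[p, f, ] else 1)
        pr <- c(pr_sub, model$ins_rate, model$del_rate)
        k <- sample.int(6L, 1L, prob = pr)
        ev[[h]] <- if (k <= 4L) c(1L, k) # substitution to base k
        else if (k == 5L) c(2L, sample.int(4L, 1L)) # insertion of random base
        else c(3L, 0L) # deletion
      }
      # assemble molecules
      by_mol <- split(seq_along(hit), mol_of)
      for (mi in mols_t) {
        key <- as.character(mi)
        hs <- by_mol[[key]]
        if (is.null(hs)) {
          molecules[[mi]] <- list(id = mi, transcript_id = tx$id[t],
                                  seq = tmpl, refpos = NULL)
          next
        }
        o <- order(pos[hs])
        hs <- hs[o]
        hs <- hs[!duplicated(pos[hs])] # at most one event per base
        types <- vapply(ev[hs], `[`, integer(1), 1L)
        vals <- vapply(ev[hs], `[`, integer(1), 2L)
        ps <- pos[hs]
        sq <- tmpl
        keep <- rep(TRUE, len)
        ins_at <- integer(0); ins_base <- integer(0)
        for (j in seq_along(hs)) {
          if (types[j] == 1L) {
            if (vals[j] == tmpl[ps[j]]) next # self-substitution impossible; guard
            sq[ps[j]] <- vals[j]
          } else if (types[j] == 2L) {
            ins_at <- c(ins_at, ps[j]); ins_base <- c(ins_base, vals[j])
          } else keep[ps[j]] <- FALSE
          led_mol <- c(led_mol, mi); led_tx <- c(led_tx, tx$id[t])
          led_pos <- c(led_pos, ps[j] - 1L)
          led_type <- c(led_type, c("sub", "ins", "del")[types[j]])
          led_from <- c(led_from, tmpl[ps[j]])
          led_to <- c(led_to, if (types[j] == 3L) NA_integer_ else vals[j])
        }
        refpos <- seq_len(len) - 1L
        if (length(ins_at) > 0L || any(!keep)) {
          pieces_seq <- list(); pieces_ref <- list()
          last <- 1L
          for (j in seq_along(ins_at)) {
            a <- ins_at[j]
            pre <- if (a > last) last:(a - 1L) else integer(0)
            pre <- pre[keep[pre]]
            pieces_seq[[length(pieces_seq) + 1L]] <- c(sq[pre], ins_base[j])
            pieces_ref[[length(pieces_ref) + 1L]] <- c(refpos[pre], NA_integer_)
            last <- a
          }
          tail_idx <- last:len
          tail_idx <- tail_idx[keep[tail_idx]]
          pieces_seq[[length(pieces_seq) + 1L]] <- sq[tail_idx]
          pieces_ref[[length(pieces_ref) + 1L]] <- refpos[tail_idx]
          sq <- unlist(pieces_seq); refpos <- unlist(pieces_ref)
          molecules[[mi]] <- list(id = mi, transcript_id = tx$id[t],
                                  seq = sq, refpos = refpos)
        } else {
          molecules[[mi]] <- list(id = mi, transcript_id = tx$id[t],
                                  seq = sq, refpos = NULL)
        }
      }
    }
    ledger <- tibble::tibble(
      molecule_id = led_mol, transcript_id = led_tx, position = led_pos,
      type = led_type,
      from_base = BASES[led_from],
      to_base = ifelse(is.na(led_to), NA_character_, BASES[led_to])
    )
    ledger <- ledger[order(ledger$molecule_id, ledger$position), ]
    structure(list(molecules = molecules, ledger = ledger,
                   base_counts = stats::setNames(base_counts, BASES)),
              class = "molecule_set")
  })
}

#' @export
print.molecule_set <- function(x, ...) {
  cat("<molecule_set> ", length(x$molecules), " molecules, ",
      nrow(x$ledger), " injected errors\n", sep = "")
  invisible(x)
}

#' Molecule sequences as character strings
#'
#' @param ms A `molecule_set`.
#' @return Character vector of mutated molecule sequences.
#' @export
molecule_sequences <- function(ms) {
  vapply(ms$molecules, function(m) codes_to_dna(m$seq), character(1))
}
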