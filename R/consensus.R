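# Tandem-repeat consensus calling. A read is partitioned into repeat copies
# at the detected period; per position, only copies with quality >= Q20 are
# counted and (in the default unanimity mode) the position is called only if
# at least `min_repeats` qualifying copies exist and all of them agree.
# Everything else is masked and excluded from both error and denominator
# counts, which is what confines once-per-copy artifacts to (miscall/3)^3
# chance concordance.

#' Detect the tandem-repeat period of a read
#'
#' Finds the period `p` in `[min_period, max_period]` maximizing the mean
#' base identity between `sequence[i]` and `sequence[i + p]`, i.e. the
#' fragment length of the rolling-circle concatemer.
#'
#' @param read A `repeat_reads` object (vectorized) or a single sequence
#'   string.
#' @param min_period,max_period Candidate period range (the fragment-length
#'   range of the library).
#' @param min_identity Minimum repeat identity to accept; below it the read
#'   is unusable and `NA` is returned.
#' @return Integer period(s); `NA` where no acceptable period exists or the
#'   read is shorter than two minimum-length repeats.
#' @examples
#' frag <- paste(sample(c("A","C","G","T"), 90, TRUE), collapse = "")
#' detect_period(strrep(frag, 4))
#' @export
detect_period <- function(read, min_period = 80L, max_period = 100L,
                          min_identity = 0.85) {
  M <- if (inherits(read, "repeat_reads")) read$seq
       else strings_to_code_matrix(as.character(read))
  p <- detect_periods_matrix(M, min_period, max_period, min_identity)
  if (is.character(read) && length(read) == 1L) p[1] else p
}

detect_periods_matrix <- function(M, min_period = 80L, max_period = 100L,
                                  min_identity = 0.85) {
  storage.mode(M) <- "integer"
  detect_periods_cpp(M, as.integer(min_period), as.integer(max_period),
                     min_identity)
}

#' Build the consensus of one tandem-repeat read
#'
#' @param read Sequence string (or a 1-read `repeat_reads` object).
#' @param qual Integer Phred vector (omit when `read` is a `repeat_reads`).
#' @param period Repeat period from [detect_period()].
#' @param q_cutoff Quality score cutoff; repeat-copy bases below it do not
#'   count (default 20).
#' @param min_repeats Minimum qualifying copies for a position call, and
#'   minimum full copies for the read to be usable at all (default 3).
#' @param mode `"unanimity"` (default: all qualifying copies must agree) or
#'   `"majority"` (strict majority of qualifying copies).
#' @return A `consensus_fragment` (list with `sequence` — masked positions
#'   as `N` —, `called`, `n_cov`, `n_q`, `n_agree`, `min_q`, `period`), or
#'   `NULL` if the read has fewer than `min_repeats` full copies.
#' @export
build_consensus <- function(read, qual = NULL, period, q_cutoff = 20L,
                            min_repeats = 3L, mode = c("unanimity", "majority")) {
  mode <- match.arg(mode)
  if (period <= 0L) stop_param("period must be positive")
  if (inherits(read, "repeat_reads")) {
    M <- read$seq; Q <- read$qual
  } else {
    M <- strings_to_code_matrix(as.character(read))
    Q <- matrix(as.integer(qual), nrow = 1L, ncol = ncol(M))
  }
  cb <- consensus_matrix(M, Q, period, q_cutoff, min_repeats, mode)
  if (!cb$ok[1]) return(NULL)
  cons <- cb$cons[1, ]
  support <- consensus_support(M[1, ], Q[1, ], cons, period, q_cutoff)
  structure(list(
    sequence = codes_to_dna(cons),
    called = !is.na(cons),
    codes = cons,
    n_cov = support$n_cov, n_q = support$n_q,
    n_agree = support$n_agree, min_q = support$min_q,
    period = as.integer(period)
  ), class = "consensus_fragment")
}

#' @export
print.consensus_fragment <- function(x, ...) {
  cat("<consensus_fragment> period ", x$period, ", ",
      sum(x$called), "/", length(x$called), " positions called\n", sep = "")
  invisible(x)
}

# Batched consensus over reads sharing one period.
# M, Q: n x W integer matrices. Returns cons (n x period, NA = masked),
# n_q matrix, and per-read acceptance (>= min_repeats full copies).
consensus_matrix <- function(M, Q, period, q_cutoff, min_repeats,
                             mode = "unanimity") {
  n <- nrow(M); W <- ncol(M)
  p <- as.integer(period)
  k <- ceiling(W / p)
  widths <- rowSums(!is.na(M))
  ok <- (widths %/% p) >= min_repeats
  nq <- matrix(0L, n, p)
  if (mode == "unanimity") {
    vmin <- matrix(NA_integer_, n, p); vmax <- matrix(NA_integer_, n, p)
  } else {
    cnt <- lapply(1:4, function(b) matrix(0L, n, p))
  }
  for (cpy in seq_len(k)) {
    cols <- ((cpy - 1L) * p + 1L):min(cpy * p, W)
    m <- matrix(NA_integer_, n, p); q <- matrix(NA_integer_, n, p)
    m[, seq_along(cols)] <- M[, cols, drop = FALSE]
    q[, seq_along(cols)] <- Q[, cols, drop = FALSE]
    qual <- !is.na(m) & !is.na(q) & q >= q_cutoff
    m[!qual] <- NA_integer_
    nq <- nq + qual
    if (mode == "unanimity") {
      vmin <- pmin(vmin, m, na.rm = TRUE)
      vmax <- pmax(vmax, m, na.rm = TRUE)
    } else {
      for (b in 1:4) cnt[[b]] <- cnt[[b]] + (qual & m == b)
    }
  }
  if (mode == "unanimity") {
    called <- !is.na(vmin) & nq >= min_repeats & vmin == vmax
    cons <- vmax
  } else {
    top <- pmax(cnt[[1]], cnt[[2]], cnt[[3]], cnt[[4]])
    n_top <- (cnt[[1]] == top) + (cnt[[2]] == top) + (cnt[[3]] == top) +
      (cnt[[4]] == top)
    called <- nq >= min_repeats & top > nq / 2 & n_top == 1L
    cons <- matrix(NA_integer_, nrow(top), ncol(top))
    for (b in 4:1) cons[cnt[[b]] == top & top > 0L] <- b
  }
  cons[!called] <- NA_integer_
  cons[!ok, ] <- NA_integer_
  list(cons = cons, n_q = nq, ok = ok)
}

# Per-position support detail for the single-read API.
consensus_support <- function(seq_v, qual_v, cons, p, q_cutoff) {
  W <- length(seq_v)
  k <- ceiling(W / p)
  n_cov <- integer(p); n_q <- integer(p); n_agree <- integer(p)
  min_q <- rep(NA_integer_, p)
  for (cpy in seq_len(k)) {
    idx <- (cpy - 1L) * p + seq_len(p)
    valid <- idx <= W
    b <- rep(NA_integer_, p); q <- rep(NA_integer_, p)
    b[valid] <- seq_v[idx[valid]]; q[valid] <- qual_v[idx[valid]]
    cov <- !is.na(b)
    qual <- cov & !is.na(q) & q >= q_cutoff
    n_cov <- n_cov + cov
    n_q <- n_q + qual
    n_agree <- n_agree + (qual & !is.na(cons) & b == cons)
    upd <- qual & (is.na(min_q) | q < min_q)
    min_q[upd] <- q[upd]
  }
  list(n_cov = n_cov, n_q = n_q, n_agree = n_agree, min_q = min_q)
}
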