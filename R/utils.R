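# Internal coding: A=1, C=2, G=3, T=4. Everything hot-path works on integer
# code matrices; strings only exist at the FASTA/FASTQ boundary.

BASES <- c("A", "C", "G", "T")

.code_lookup <- local({
  x <- rep(NA_integer_, 256L)
  x[utf8ToInt("A")] <- 1L
  x[utf8ToInt("C")] <- 2L
  x[utf8ToInt("G")] <- 3L
  x[utf8ToInt("T")] <- 4L
  x
})

dna_to_codes <- function(s) {
  .code_lookup[utf8ToInt(s)]
}

codes_to_dna <- function(v) {
  # NA (masked) positions render as N
  chr <- c(65L, 67L, 71L, 84L)[v]
  chr[is.na(chr)] <- 78L
  intToUtf8(chr)
}

# n strings of possibly unequal length -> n x width integer code matrix,
# NA beyond each string's end
strings_to_code_matrix <- function(seqs, width = NULL) {
  lens <- nchar(seqs)
  if (is.null(width)) width <- max(lens, 0L)
  m <- matrix(NA_integer_, length(seqs), width)
  if (length(seqs) == 0L || width == 0L) return(m)
  flat <- .code_lookup[utf8ToInt(paste(seqs, collapse = ""))]
  m[cbind(rep(seq_along(seqs), lens), sequence(lens))] <- flat
  m
}

# Phred+33 quality strings -> integer matrix
qual_strings_to_matrix <- function(quals, width = NULL) {
  lens <- nchar(quals)
  if (is.null(width)) width <- max(lens, 0L)
  m <- matrix(NA_integer_, length(quals), width)
  if (length(quals) == 0L || width == 0L) return(m)
  flat <- utf8ToInt(paste(quals, collapse = "")) - 33L
  m[cbind(rep(seq_along(quals), lens), sequence(lens))] <- flat
  m
}

code_row_to_string <- function(v) {
  v <- v[!is.na(v)]
  intToUtf8(c(65L, 67L, 71L, 84L)[v])
}

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# NULL seed means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("txerror_parameter_error", "error")))
}

#' The twelve substitution types
#'
#' All ordered `from > to` base pairs over `{A, C, G, T}`, in the fixed
#' order used throughout rate tables and figures.
#'
#' @return Character vector of length 12, e.g. `"A>C"`, `"A>G"`, ...
#' @export
sub_types <- function() {
  out <- character(0)
  for (f in BASES) for (t in BASES) if (f != t) out <- c(out, paste0(f, ">", t))
  out
}

# "A>C" -> c(1L, 2L)
sub_type_codes <- function(type) {
  c(match(substr(type, 1L, 1L), BASES), match(substr(type, 3L, 3L), BASES))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# n uniform integer draws from [lo, hi]; safe when lo == hi
sample_range <- function(lo, hi, n) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}
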