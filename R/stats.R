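# Small-sample statistics for the factorial knockout design. The designs
# here are tiny (two replicates per genotype, eight values per grouping),
# so the Mann-Whitney test is computed exactly by enumerating all label
# assignments; Fisher's exact test and Benjamini-Hochberg correction are
# delegated to the standard implementations in `stats`, whose definitions
# coincide with the ones used here.

#' Exact Mann-Whitney U test
#'
#' Computes the U statistic for `x` and a two-sided p-value. For total
#' sample sizes up to `exact_limit` the null distribution is enumerated
#' over all `choose(nx+ny, nx)` label assignments (ties included), and the
#' two-sided p doubles the smaller tail, capped at 1. Larger samples use
#' the normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric vectors (non-empty).
#' @param exact_limit Maximum `length(x) + length(y)` for exact enumeration
#'   (default 20).
#' @return List with `U` (for `x`) and `p.value`.
#' @examples
#' mann_whitney_exact(1:8, 9:16)$p.value # complete separation: 2/12870
#' @export
mann_whitney_exact <- function(x, y, exact_limit = 20L) {
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) stop_param("both groups must be non-empty")
  if (anyNA(c(x, y))) stop_param("missing values not allowed")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  n <- nx + ny
  if (n <= exact_limit) {
    cmb <- utils::combn(n, nx)
    Us <- colSums(matrix(r[cmb], nrow = nx)) - nx * (nx + 1) / 2
    eps <- 1e-9
    p_lo <- mean(Us <= U + eps)
    p_hi <- mean(Us >= U - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- nx * ny / 2
    tie <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = U, p.value = 1))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p.value = p)
}

#' Unpaired two-sample t-test
#'
#' Student's pooled-variance test by default (`var_equal = TRUE`), Welch by
#' flag. Degenerate inputs are resolved explicitly: zero variance in both
#' groups gives p = 1 for equal means, and p = 0 with a `degenerate` flag
#' for unequal means.
#'
#' @param x,y Numeric vectors of length >= 2.
#' @param var_equal Pooled (TRUE, default) or Welch (FALSE).
#' @return List with `t`, `df`, `p.value`, `degenerate`.
#' @export
t_test_unpaired <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L)
    stop_param("both groups need at least two values")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p.value = 1,
                  degenerate = TRUE))
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p.value = 0,
                degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, degenerate = FALSE)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' p is the sum of hypergeometric probabilities of all tables with the
#' observed margins whose probability does not exceed the observed
#' table's. A table with a zero margin carries no information and returns
#' p = 1.
#'
#' @param m 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(0, 5, 5, 0), 2)) # 2/252
#' @export
fisher_exact_2x2 <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(2L, 2L))) stop_param("m must be 2x2")
  if (any(m < 0) || any(m != round(m))) stop_param("counts must be ",
                                                   "non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  min(1, stats::fisher.test(m)$p.value)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Returns the step-up rejection mask at the given FDR together with the
#' adjusted q-values (`q(i) = min over j >= i of m p(j)/j` on sorted
#' p-values, capped at 1); rejection is exactly `q <= fdr`.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param fdr Target false discovery rate (default 0.05).
#' @return List with `reject` (logical) and `q` (numeric), in input order.
#' @export
benjamini_hochberg <- function(pvals, fdr = 0.05) {
  if (any(is.na(pvals)) || any(pvals < -1e-8 | pvals > 1 + 1e-8))
    stop_param("p-values must lie in [0, 1]")
  pvals <- pmin(pmax(pvals, 0), 1) # absorb floating-point spill from exact tests
  q <- stats::p.adjust(pvals, method = "BH")
  list(reject = q <= fdr, q = q)
}

#' Group replicate rates by fidelity-factor status
#'
#' Splits per-sample rates into the samples with the named gene intact
#' (`plus`) and deleted (`minus`). With the full 8-genotype x 2-replicate
#' design each side holds 8 values (4 genotypes x 2 replicates).
#'
#' @param rate_tables Row-bound per-sample `rate_table` rows (or any tibble
#'   with `sample_id` and the metric column).
#' @param design A [study_design()] tibble.
#' @param gene `"greA"`, `"greB"` or `"dksA"`.
#' @param metric Column to extract (default `"R"`, the overall rate).
#' @return A `grouped_rates` list: `gene`, `metric`, `plus`, `minus`,
#'   and the corresponding sample ids.
#' @export
group_by_gene <- function(rate_tables, design, gene, metric = "R") {
  if (!gene %in% c("greA", "greB", "dksA")) stop_param("unknown gene ", gene)
  if (!metric %in% names(rate_tables)) stop_param("no column ", metric)
  merged <- dplyr::left_join(rate_tables, design, by = "sample_id")
  if (anyNA(merged[[gene]])) stop_param("samples missing from the design")
  structure(list(
    gene = gene, metric = metric,
    plus = merged[[metric]][merged[[gene]]],
    minus = merged[[metric]][!merged[[gene]]],
    samples_plus = merged$sample_id[merged[[gene]]],
    samples_minus = merged$sample_id[!merged[[gene]]]
  ), class = "grouped_rates")
}

#' @export
print.grouped_rates <- function(x, ...) {
  cat("<grouped_rates> ", x$gene, " on ", x$metric, ": ",
      length(x$plus), " intact vs ", length(x$minus), " deleted\n", sep = "")
  invisible(x)
}

#' Fidelity-factor grouping tests
#'
#' For each gene (greA, greB, dksA), compares gene-intact against
#' gene-deleted samples: the overall error rate by exact Mann-Whitney U and
#' Student's t, and each of the twelve composition-normalized substitution
#' rates by Mann-Whitney with Benjamini-Hochberg correction across the
#' twelve types within the gene.
#'
#' @param rate_tables Row-bound per-sample `rate_table` rows.
#' @param design A [study_design()] tibble.
#' @param fdr False discovery rate for the per-type families.
#' @return List of tibbles: `overall` (gene, U, p_mw, t, p_t) and
#'   `per_type` (gene, type, U, p, q, rejected).
#' @export
fidelity_factor_tests <- function(rate_tables, design, fdr = 0.05) {
  genes <- c("greA", "greB", "dksA")
  overall <- dplyr::bind_rows(lapply(genes, function(g) {
    gr <- group_by_gene(rate_tables, design, g, metric = "R")
    mw <- mann_whitney_exact(gr$plus, gr$minus)
    tt <- t_test_unpaired(gr$plus, gr$minus)
    tibble::tibble(gene = g, n_plus = length(gr$plus),
                   n_minus = length(gr$minus),
                   mean_plus = mean(gr$plus), mean_minus = mean(gr$minus),
                   U = mw$U, p_mw = mw$p.value, t = tt$t, p_t = tt$p.value)
  }))
  per_type <- dplyr::bind_rows(lapply(genes, function(g) {
    rows <- lapply(sub_types(), function(ty) {
      col <- paste0("Rn_", sub(">", "", ty, fixed = TRUE))
      gr <- group_by_gene(rate_tables, design, g, metric = col)
      mw <- mann_whitney_exact(gr$plus, gr$minus)
      tibble::tibble(gene = g, type = ty, mean_plus = mean(gr$plus),
                     mean_minus = mean(gr$minus), U = mw$U, p = mw$p.value)
    })
    out <- dplyr::bind_rows(rows)
    bh <- benjamini_hochberg(out$p, fdr = fdr)
    out$q <- bh$q
    out$rejected <- bh$reject
    out
  }))
  list(overall = overall, per_type = per_type)
}

#' Per-strain comparisons against the wildtype
#'
#' Unpaired Student's t-tests of each mutant genotype against the wildtype
#' (n = replicates per side): the overall rate, and each substitution type
#' with Benjamini-Hochberg correction across the twelve types within each
#' genotype.
#'
#' @inheritParams fidelity_factor_tests
#' @return List of tibbles `overall` and `per_type`.
#' @export
strain_vs_wt_tests <- function(rate_tables, design, fdr = 0.05) {
  merged <- dplyr::left_join(rate_tables, design, by = "sample_id")
  wt <- merged[merged$genotype == "WT", ]
  muts <- setdiff(unique(merged$genotype), "WT")
  overall <- dplyr::bind_rows(lapply(muts, function(g) {
    mu <- merged[merged$genotype == g, ]
    tt <- t_test_unpaired(mu$R, wt$R)
    tibble::tibble(genotype = g, mean_mut = mean(mu$R), mean_wt = mean(wt$R),
                   t = tt$t, p = tt$p.value, degenerate = tt$degenerate)
  }))
  per_type <- dplyr::bind_rows(lapply(muts, function(g) {
    mu <- merged[merged$genotype == g, ]
    rows <- lapply(sub_types(), function(ty) {
      col <- paste0("Rn_", sub(">", "", ty, fixed = TRUE))
      tt <- t_test_unpaired(mu[[col]], wt[[col]])
      tibble::tibble(genotype = g, type = ty, t = tt$t, p = tt$p.value)
    })
    out <- dplyr::bind_rows(rows)
    bh <- benjamini_hochberg(out$p, fdr = fdr)
    out$q <- bh$q
    out$rejected <- bh$reject
    out
  }))
  list(overall = overall, per_type = per_type)
}
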