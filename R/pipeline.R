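# End-to-end workflow: simulate the factorial study, call errors per
# sample, build rate tables, run the grouping statistics and the hybrid
# context analysis, and (optionally) write every stage to TSV/FASTA/FASTQ
# so downstream stages can be reproduced from files.

#' Configuration for a full pipeline run
#'
#' Collects every tunable of the study in one validated object. Defaults
#' are the desk-scale study conditions: 50 transcripts of 0.8-1.2 kb, the
#' eight-genotype x two-replicate factorial design, 2e4 reads per sample,
#' the [default_error_model()] rates with G>A tripled in greA-deleted
#' genotypes, Q20 consensus cutoff, three-repeat minimum, nine-base hybrid
#' window, 1e6 Monte Carlo draws per focal base and FDR 0.05.
#'
#' @param seed Master seed; all per-sample seeds derive from it.
#' @param n_transcripts,length_range,gc_fraction Transcriptome parameters.
#' @param replicates Replicates per genotype.
#' @param reads_per_sample Tandem-repeat reads per sample.
#' @param model Base [error_model()] shared by all genotypes.
#' @param grea_ga_multiplier G>A rate multiplier applied in greA-deleted
#'   genotypes (default 3).
#' @param grea_context_multipliers Optional context multipliers (named as
#'   in [error_model()]) applied in greA-deleted genotypes only.
#' @param q_cutoff,min_repeats Consensus thresholds.
#' @param depth Hybrid context window.
#' @param mc_samples Monte Carlo draws per focal base.
#' @param fdr False discovery rate for all BH families.
#' @param write_fastq Whether [run_pipeline()] writes per-sample FASTQ.
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1L, n_transcripts = 50L,
                       length_range = c(800L, 1200L), gc_fraction = 0.5,
                       replicates = 2L, reads_per_sample = 20000L,
                       model = default_error_model(),
                       grea_ga_multiplier = 3,
                       grea_context_multipliers = NULL,
                       q_cutoff = 20L, min_repeats = 3L, depth = 9L,
                       mc_samples = 1e6, fdr = 0.05, write_fastq = TRUE) {
  cfg <- list(seed = as.integer(seed), n_transcripts = as.integer(n_transcripts),
              length_range = as.integer(length_range),
              gc_fraction = gc_fraction, replicates = as.integer(replicates),
              reads_per_sample = as.integer(reads_per_sample), model = model,
              grea_ga_multiplier = grea_ga_multiplier,
              grea_context_multipliers = grea_context_multipliers,
              q_cutoff = as.integer(q_cutoff),
              min_repeats = as.integer(min_repeats),
              depth = as.integer(depth), mc_samples = mc_samples, fdr = fdr,
              write_fastq = isTRUE(write_fastq))
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  if (!inherits(cfg$model, "error_model")) stop_param("model must be an error_model")
  if (cfg$q_cutoff < 0 || cfg$q_cutoff > 41) stop_param("q_cutoff out of range")
  if (cfg$min_repeats < 1) stop_param("min_repeats must be >= 1")
  if (cfg$depth < 1 || cfg$depth > 50) stop_param("depth out of range")
  if (cfg$fdr <= 0 || cfg$fdr >= 1) stop_param("fdr must be in (0, 1)")
  if (cfg$reads_per_sample < 1) stop_param("reads_per_sample must be >= 1")
  if (cfg$grea_ga_multiplier <= 0) stop_param("multiplier must be positive")
  invisible(cfg)
}

# serializable echo of a config (error_model flattened to plain lists)
config_as_list <- function(cfg) {
  m <- cfg$model
  out <- unclass(cfg)
  out$model <- list(
    sub_rates = as.list(vapply(stats::setNames(sub_types(), sub_types()),
                               function(ty) {
                                 ft <- sub_type_codes(ty)
                                 m$sub[ft[1], ft[2]]
                               }, numeric(1))),
    ins_rate = m$ins_rate, del_rate = m$del_rate,
    seq_error_rate = m$seq_error_rate,
    quality_correct = m$quality_correct, quality_error = m$quality_error,
    context_multipliers = {
      idx <- which(m$mult != 1, arr.ind = TRUE)
      if (nrow(idx) == 0) NULL else
        as.list(stats::setNames(m$mult[idx], apply(idx, 1, function(r)
          sprintf("%s:%s>%s", BASES[r[1]], BASES[r[2]], BASES[r[3]]))))
    })
  out$grea_context_multipliers <- if (is.null(cfg$grea_context_multipliers))
    NULL else as.list(cfg$grea_context_multipliers)
  out
}

#' Write / read a run configuration as YAML
#'
#' The round trip is lossless for every setting that affects results.
#'
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @rdname config-io
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(config_as_list(cfg), path)
  invisible(path)
}

#' @rdname config-io
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  model <- error_model(
    sub_rates = unlist(raw$model$sub_rates),
    ins_rate = raw$model$ins_rate, del_rate = raw$model$del_rate,
    context_multipliers = if (!is.null(raw$model$context_multipliers))
      unlist(raw$model$context_multipliers),
    seq_error_rate = raw$model$seq_error_rate,
    quality_correct = raw$model$quality_correct,
    quality_error = raw$model$quality_error)
  run_config(seed = raw$seed, n_transcripts = raw$n_transcripts,
             length_range = raw$length_range, gc_fraction = raw$gc_fraction,
             replicates = raw$replicates,
             reads_per_sample = raw$reads_per_sample, model = model,
             grea_ga_multiplier = raw$grea_ga_multiplier,
             grea_context_multipliers = if (!is.null(raw$grea_context_multipliers))
               unlist(raw$grea_context_multipliers),
             q_cutoff = raw$q_cutoff, min_repeats = raw$min_repeats,
             depth = raw$depth, mc_samples = raw$mc_samples, fdr = raw$fdr,
             write_fastq = raw$write_fastq)
}

# per-genotype error models: greA-deleted genotypes get the elevated G>A
# rate and (optionally) the context multipliers
genotype_models <- function(cfg, design) {
  base <- cfg$model
  deleted <- base
  sub <- base$sub
  sub["G", "A"] <- sub["G", "A"] * cfg$grea_ga_multiplier
  deleted <- error_model(
    sub_rates = sub, ins_rate = base$ins_rate, del_rate = base$del_rate,
    context_multipliers = cfg$grea_context_multipliers,
    seq_error_rate = base$seq_error_rate,
    quality_correct = base$quality_correct,
    quality_error = base$quality_error)
  lapply(stats::setNames(design$greA, design$sample_id), function(intact)
    if (intact) base else deleted)
}

# molecules needed so that shearing yields at least n_reads fragments
molecules_for_reads <- function(tx, n_reads, frag_mean = 90) {
  mean_len <- mean(nchar(tx$sequence))
  per_mol <- max(1, mean_len / frag_mean - 1)
  as.integer(ceiling(n_reads / per_mol * 1.08) + 5L)
}

#' Simulate one sample's library
#'
#' Molecules are drawn until shearing yields at least `n_reads` fragments
#' (a uniform subsample caps the library at exactly `n_reads`).
#'
#' @param tx A `transcriptome`.
#' @param model The sample's [error_model()].
#' @param n_reads Reads wanted.
#' @param seed Integer seed.
#' @return List with `reads` (a `repeat_reads`), `ledger`, `base_counts`.
#' @export
simulate_sample <- function(tx, model, n_reads, seed = NULL) {
  n_mol <- molecules_for_reads(tx, n_reads)
  ms <- simulate_molecules(tx, n_mol, model, seed = seed)
  reads <- build_library(ms, model, n_reads = n_reads,
                         seed = if (is.null(seed)) NULL else seed + 1L)
  list(reads = reads, ledger = ms$ledger, base_counts = ms$base_counts,
       molecules = ms)
}

#' Run the full in-memory study
#'
#' Simulates every sample of the factorial design, calls errors, and
#' collects rate tables, events, denominators and truth ledgers. Samples
#' are processed one at a time so memory stays flat; reads are not kept.
#'
#' @param cfg A [run_config()].
#' @param keep_events Keep per-sample event tibbles and denominators
#'   (default TRUE; needed for the context analysis).
#' @return A `study_run` list: `config`, `tx`, `design`, `rate_tables`,
#'   `events` (named list), `denominators` (named list), `ledgers` (named
#'   list), `models`, `read_counts`.
#' @export
run_study <- function(cfg, keep_events = TRUE) {
  validate_run_config(cfg)
  seeds <- with_seed(cfg$seed, sample.int(2^30, 2L))
  tx <- generate_transcriptome(cfg$n_transcripts, cfg$length_range,
                               cfg$gc_fraction, seed = seeds[1])
  design <- study_design(cfg$replicates)
  models <- genotype_models(cfg, design)
  index <- build_seed_index(tx)
  sample_seeds <- with_seed(seeds[2], sample.int(2^30, nrow(design)))
  rate_tables <- list(); events <- list(); denoms <- list(); ledgers <- list()
  counts <- list()
  for (i in seq_len(nrow(design))) {
    sid <- design$sample_id[i]
    sim <- simulate_sample(tx, models[[sid]], cfg$reads_per_sample,
                           seed = sample_seeds[i])
    calls <- call_errors(sim$reads, tx, q_cutoff = cfg$q_cutoff,
                         min_repeats = cfg$min_repeats, index = index)
    rt <- rate_table(calls, sample_id = sid)
    rate_tables[[sid]] <- rt
    ledgers[[sid]] <- sim$ledger
    counts[[sid]] <- c(calls$counts,
                       n_reads = n_reads(sim$reads),
                       sim_bases = sum(sim$base_counts))
    if (keep_events) {
      events[[sid]] <- calls$events
      denoms[[sid]] <- calls$denominator
    }
    attr(ledgers[[sid]], "base_counts") <- sim$base_counts
  }
  structure(list(config = cfg, tx = tx, design = design,
                 rate_tables = dplyr::bind_rows(rate_tables),
                 events = events, denominators = denoms, ledgers = ledgers,
                 models = models, read_counts = counts),
            class = "study_run")
}

#' @export
print.study_run <- function(x, ...) {
  cat("<study_run> ", nrow(x$design), " samples, ",
      sum(x$rate_tables$E), " called errors over ",
      format(sum(x$rate_tables$N), big.mark = ","), " bases\n", sep = "")
  invisible(x)
}

# pooled events and coverage for a set of samples
pool_samples <- function(study, sample_ids) {
  ev <- dplyr::bind_rows(study$events[sample_ids])
  cov <- study$denominators[[sample_ids[1]]]$coverage
  if (length(sample_ids) > 1) {
    for (sid in sample_ids[-1]) {
      c2 <- study$denominators[[sid]]$coverage
      for (k in seq_along(cov)) cov[[k]] <- cov[[k]] + c2[[k]]
    }
  }
  names(cov) <- study$tx$id
  list(events = ev, coverage = cov)
}

#' Hybrid-context analysis of a study run
#'
#' Pools errors by greA status, computes the Monte Carlo background from
#' the pooled sequencing depth, tests the position-by-base composition
#' grid between the groups, and compares preceding-nucleotide conditional
#' rates per sample group.
#'
#' @param study A [run_study()] result (with events kept).
#' @param seed Seed for the Monte Carlo background.
#' @return List with `background`, `enrichment` (a `context_enrichment`),
#'   `context_rates` (per-sample, row-bound) and `rate_tests`.
#' @export
context_analysis <- function(study, seed = NULL) {
  if (length(study$events) == 0L)
    stop_param("study was run with keep_events = FALSE")
  design <- study$design
  plus <- design$sample_id[design$greA]
  minus <- design$sample_id[!design$greA]
  pp <- pool_samples(study, plus)
  pm <- pool_samples(study, minus)
  cov_all <- pp$coverage
  for (k in seq_along(cov_all)) cov_all[[k]] <- cov_all[[k]] + pm$coverage[[k]]
  bg <- background_composition(study$tx, coverage = cov_all,
                               n_samples = study$config$mc_samples,
                               depth = study$config$depth, seed = seed)
  subs_p <- pp$events[pp$events$type == "sub", ]
  subs_m <- pm$events[pm$events$type == "sub", ]
  enr <- composition_enrichment(subs_p, subs_m, study$tx, bg,
                                labels = c("greA+", "greA-"),
                                depth = study$config$depth,
                                fdr = study$config$fdr)
  cr <- dplyr::bind_rows(lapply(design$sample_id, function(sid)
    per_type_context_rates(study$events[[sid]],
                           study$denominators[[sid]]$dinuc, study$tx,
                           sample_id = sid)))
  tests <- context_rate_tests(cr, design, gene = "greA",
                              fdr = study$config$fdr)
  list(background = bg, enrichment = enr, context_rates = cr,
       rate_tests = tests)
}

#' Truth-versus-estimate recovery report
#'
#' For every sample and error type, compares the injected per-base rate
#' (from the sample's generating model), the realized rate in the truth
#' ledger (injected events over simulated template bases), and the
#' estimated composition-normalized rate, with a Clopper-Pearson 95%
#' binomial interval on the estimate.
#'
#' @param study A [run_study()] result.
#' @return A tibble with one row per (sample, type); the fraction of rows
#'   whose interval covers the injected and realized rates is attached as
#'   attributes `coverage_injected` and `coverage_realized`.
#' @export
recovery_report <- function(study) {
  types <- sub_types()
  rows <- list()
  for (sid in study$design$sample_id) {
    model <- study$models[[sid]]
    ledger <- study$ledgers[[sid]]
    bc <- attr(ledger, "base_counts")
    rt <- study$rate_tables[study$rate_tables$sample_id == sid, ]
    if (nrow(rt) == 0L) stop_param("rate table missing for sample ", sid)
    for (ty in types) {
      ft <- sub_type_codes(ty)
      key <- sub(">", "", ty, fixed = TRUE)
      injected <- model$sub[ft[1], ft[2]]
      n_led <- sum(ledger$type == "sub" & ledger$from_base == BASES[ft[1]] &
                     ledger$to_base == BASES[ft[2]])
      realized <- n_led / bc[[BASES[ft[1]]]]
      E <- rt[[paste0("E_", key)]]
      Nx <- rt[[paste0("N_", BASES[ft[1]])]]
      ci <- if (Nx > 0) stats::binom.test(E, Nx)$conf.int else c(NA, NA)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sid, type = ty, injected = injected,
        realized = realized, estimated = rt[[paste0("Rn_", key)]],
        ci_lo = ci[1], ci_hi = ci[2],
        covers_injected = !is.na(ci[1]) & injected >= ci[1] & injected <= ci[2],
        covers_realized = !is.na(ci[1]) & realized >= ci[1] & realized <= ci[2])
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "coverage_injected") <- mean(out$covers_injected)
  attr(out, "coverage_realized") <- mean(out$covers_realized)
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Recompute rate tables from written stage files
#'
#' Re-derives every per-sample rate table from the `events.tsv` and
#' `denominators.tsv` a previous [run_pipeline()] run wrote, so downstream
#' results can be reproduced without re-running simulation or consensus.
#'
#' @param events_path,denominators_path TSV paths from a pipeline run.
#' @return Row-bound `rate_table` rows, one per sample.
#' @export
rates_from_files <- function(events_path, denominators_path) {
  ev <- utils::read.delim(events_path, stringsAsFactors = FALSE)
  den <- utils::read.delim(denominators_path, stringsAsFactors = FALSE)
  dplyr::bind_rows(lapply(den$sample_id, function(sid) {
    d <- den[den$sample_id == sid, ]
    e <- tibble::as_tibble(ev[ev$sample_id == sid, , drop = FALSE])
    per_type_rates(e, d$N,
                   stats::setNames(c(d$N_A, d$N_C, d$N_G, d$N_T), BASES),
                   sample_id = sid)
  }))
}

#' Run the pipeline end to end and write all outputs
#'
#' Simulation, consensus calling, rate tables, grouping statistics,
#' context analysis and the recovery report, written to `out_dir` as
#' FASTA/FASTQ/TSV plus a YAML echo of the configuration and a plain-text
#' log. Re-running with the same config reproduces every table.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created; must be writable).
#' @return Invisibly, the `study_run` with the analysis results attached
#'   (`$tests`, `$strain_tests`, `$context`, `$recovery`).
#' @export
run_pipeline <- function(cfg, out_dir) {
  validate_run_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_param("cannot create output directory")
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                            "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("txerror ", as.character(utils::packageVersion("txerror")),
       ", R ", paste(R.version$major, R.version$minor, sep = "."))
  logf("seed ", cfg$seed)
  write_config(cfg, file.path(out_dir, "config.yaml"))

  study <- run_study(cfg, keep_events = TRUE)
  write_transcriptome_fasta(study$tx, file.path(out_dir, "transcriptome.fasta"))
  write_tsv(study$tx[, c("id", "weight")], file.path(out_dir, "weights.tsv"))
  write_tsv(study$design, file.path(out_dir, "design.tsv"))

  if (cfg$write_fastq) {
    # regenerate reads deterministically for the FASTQ record
    seeds <- with_seed(cfg$seed, sample.int(2^30, 2L))
    sample_seeds <- with_seed(seeds[2], sample.int(2^30, nrow(study$design)))
    fq_dir <- file.path(out_dir, "fastq")
    dir.create(fq_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(study$design))) {
      sid <- study$design$sample_id[i]
      sim <- simulate_sample(study$tx, study$models[[sid]],
                             cfg$reads_per_sample, seed = sample_seeds[i])
      write_fastq(sim$reads, file.path(fq_dir, paste0(sid, ".fastq")))
    }
    logf("wrote per-sample FASTQ")
  }

  ledger_all <- dplyr::bind_rows(lapply(names(study$ledgers), function(sid) {
    l <- study$ledgers[[sid]]
    l$sample_id <- sid
    l
  }))
  write_tsv(ledger_all, file.path(out_dir, "truth_ledger.tsv"))

  events_all <- dplyr::bind_rows(lapply(names(study$events), function(sid) {
    e <- study$events[[sid]]
    e$sample_id <- sid
    e
  }))
  write_tsv(events_all, file.path(out_dir, "events.tsv"))
  den_all <- dplyr::bind_rows(lapply(names(study$denominators), function(sid) {
    d <- study$denominators[[sid]]
    tibble::tibble(sample_id = sid, N = d$N, N_A = d$N_b[["A"]],
                   N_C = d$N_b[["C"]], N_G = d$N_b[["G"]],
                   N_T = d$N_b[["T"]])
  }))
  write_tsv(den_all, file.path(out_dir, "denominators.tsv"))
  write_tsv(study$rate_tables, file.path(out_dir, "rate_tables.tsv"))
  write_tsv(rates_long(study$rate_tables), file.path(out_dir, "rates_long.tsv"))

  tests <- fidelity_factor_tests(study$rate_tables, study$design,
                                 fdr = cfg$fdr)
  write_tsv(tests$overall, file.path(out_dir, "group_tests_overall.tsv"))
  write_tsv(tests$per_type, file.path(out_dir, "group_tests_per_type.tsv"))
  strain <- strain_vs_wt_tests(study$rate_tables, study$design, fdr = cfg$fdr)
  write_tsv(strain$overall, file.path(out_dir, "strain_tests_overall.tsv"))
  write_tsv(strain$per_type, file.path(out_dir, "strain_tests_per_type.tsv"))

  ctx_seed <- with_seed(cfg$seed + 1L, sample.int(2^30, 1L))
  ctx <- context_analysis(study, seed = ctx_seed)
  write_tsv(ctx$enrichment$profile, file.path(out_dir, "context_profile.tsv"))
  write_tsv(ctx$enrichment$tests, file.path(out_dir, "context_tests.tsv"))
  write_tsv(ctx$context_rates, file.path(out_dir, "context_rates.tsv"))
  write_tsv(ctx$rate_tests, file.path(out_dir, "context_rate_tests.tsv"))

  rec <- recovery_report(study)
  write_tsv(rec, file.path(out_dir, "recovery.tsv"))
  logf(sprintf("recovery: %.1f%% of (sample, type) intervals cover the %s",
               100 * attr(rec, "coverage_realized"), "realized rate"))
  logf("done")
  study$tests <- tests
  study$strain_tests <- strain
  study$context <- ctx
  study$recovery <- rec
  invisible(study)
}
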