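test_that("upstream context reads the reference 5' of the event", {
  tx <- tiny_tx("CCCCCCCCCG")
  ev <- tibble::tibble(transcript_id = "t01", position = 9L)
  expect_identical(upstream_context(ev, tx), "CCCCCCCCC")
  # boundary: an error at the transcript start has no context
  expect_identical(upstream_context(tibble::tibble(transcript_id = "t01",
                                                   position = 0L), tx), "")
  # truncation short of the full window
  expect_identical(upstream_context(tibble::tibble(transcript_id = "t01",
                                                   position = 3L), tx), "CCC")
  # direct-indexing oracle on random events
  tx2 <- generate_transcriptome(3, c(300, 400), 0.5, seed = 1)
  set.seed(2)
  ev2 <- tibble::tibble(
    transcript_id = sample(tx2$id, 30, replace = TRUE),
    position = sample(10:200, 30))
  ctx <- upstream_context(ev2, tx2, depth = 9)
  for (i in seq_len(30)) {
    s <- tx2$sequence[tx2$id == ev2$transcript_id[i]]
    expected <- paste(rev(strsplit(substr(s, ev2$position[i] - 8,
                                          ev2$position[i]), "")[[1]]),
                      collapse = "")
    expect_identical(ctx[i], expected)
  }
})

test_that("background composition matches closed-form cases", {
  # alternating sequence: before every A sits a C and vice versa
  tx <- tiny_tx(strrep("AC", 200))
  bg <- background_composition(tx, n_samples = 2e4, depth = 2, seed = 3,
                               focal = c("A", "C"))
  expect_equal(bg$prop["A", 1, "C"], 1)
  expect_equal(bg$prop["C", 1, "A"], 1)
  expect_equal(bg$prop["A", 2, "A"], 1)
  expect_error(background_composition(tiny_tx("AAAA"), n_samples = 10),
               class = "txerror_parameter_error")
})

test_that("Monte Carlo background converges to exhaustive enumeration", {
  tx <- generate_transcriptome(4, c(900, 1100), 0.45, seed = 4)
  exact <- oracle_background_exact(tx, depth = 9)
  bg <- background_composition(tx, n_samples = 2e5, depth = 9, seed = 5)
  for (f in 1:4) for (d in 1:9) for (b in 1:4) {
    se <- sqrt(exact[f, d, b] * (1 - exact[f, d, b]) / bg$n_valid[f, d])
    expect_lt(abs(bg$prop[f, d, b] - exact[f, d, b]), 3 * se + 1e-9)
  }
  # depth weighting: positions with zero coverage never contribute
  cov <- lapply(tx$sequence, function(s) {
    v <- rep(1L, nchar(s)); v[seq_len(nchar(s) / 2)] <- 0L; v
  })
  names(cov) <- tx$id
  exact_w <- oracle_background_exact(tx, coverage = cov, depth = 5)
  bg_w <- background_composition(tx, coverage = cov, n_samples = 2e5,
                                 depth = 5, seed = 6)
  for (f in 1:4) for (d in 1:5) for (b in 1:4) {
    se <- sqrt(exact_w[f, d, b] * (1 - exact_w[f, d, b]) / bg_w$n_valid[f, d])
    expect_lt(abs(bg_w$prop[f, d, b] - exact_w[f, d, b]), 3 * se + 1e-9)
  }
})

test_that("two Monte Carlo seeds agree within sampling error", {
  tx <- generate_transcriptome(3, c(800, 1000), 0.5, seed = 7)
  b1 <- background_composition(tx, n_samples = 1e5, depth = 3, seed = 8)
  b2 <- background_composition(tx, n_samples = 1e5, depth = 3, seed = 9)
  for (f in 1:4) for (d in 1:3) for (b in 1:4) {
    p <- (b1$prop[f, d, b] + b2$prop[f, d, b]) / 2
    se <- sqrt(2 * p * (1 - p) / b1$n_valid[f, d])
    expect_lt(abs(b1$prop[f, d, b] - b2$prop[f, d, b]), 4 * se + 1e-9)
  }
})

test_that("identical groups show no composition enrichment", {
  tx <- generate_transcriptome(3, c(500, 700), 0.5, seed = 10)
  set.seed(11)
  ev <- tibble::tibble(
    transcript_id = sample(tx$id, 200, replace = TRUE),
    position = sample(20:400, 200, replace = TRUE))
  ev$ref <- vapply(seq_len(nrow(ev)), function(i)
    substr(tx$sequence[tx$id == ev$transcript_id[i]], ev$position[i] + 1,
           ev$position[i] + 1), character(1))
  bg <- background_composition(tx, n_samples = 5e4, seed = 12)
  enr <- composition_enrichment(ev, ev, tx, bg, labels = c("a", "b"))
  expect_equal(enr$tests$p, rep(1, nrow(enr$tests)), tolerance = 1e-9)
  expect_false(any(enr$tests$rejected))
  # label symmetry
  set.seed(13)
  ev2 <- ev[sample(nrow(ev), 90), ]
  e1 <- composition_enrichment(ev, ev2, tx, bg)
  e2 <- composition_enrichment(ev2, ev, tx, bg)
  expect_equal(e1$tests$p, e2$tests$p)
  expect_error(composition_enrichment(ev[0, ], ev, tx, bg),
               class = "txerror_parameter_error")
})

test_that("uniform backgrounds leave proportions unchanged", {
  tx <- generate_transcriptome(4, c(800, 1000), 0.5, seed = 14)
  set.seed(15)
  ev <- tibble::tibble(
    transcript_id = sample(tx$id, 300, replace = TRUE),
    position = sample(20:700, 300, replace = TRUE))
  ev$ref <- vapply(seq_len(nrow(ev)), function(i)
    substr(tx$sequence[tx$id == ev$transcript_id[i]], ev$position[i] + 1,
           ev$position[i] + 1), character(1))
  bg <- background_composition(tx, n_samples = 2e5, seed = 16)
  enr <- composition_enrichment(ev, ev, tx, bg)
  pr <- enr$profile
  # GC 0.5 and independent positions: background ~uniform 0.25, so the
  # renormalized proportions stay close to the raw ones
  expect_lt(max(abs(pr$norm_prop - pr$prop), na.rm = TRUE), 0.05)
})

test_that("preceding-base rates use dinucleotide denominators", {
  tx <- tiny_tx(strrep("ACGT", 100))
  dinuc <- matrix(100, 4, 4, dimnames = list(c("A","C","G","T"),
                                             c("A","C","G","T")))
  ev <- tibble::tibble(transcript_id = "t01", position = c(2L, 6L, 10L),
                       ref = "G", obs = "A", type = "sub")
  cr <- per_type_context_rates(ev, dinuc, tx, sample_id = "s")
  expect_equal(nrow(cr), 48L)
  expect_equal(cr$rate[cr$preceding == "C" & cr$type == "G>A"], 3 / 100)
  expect_true(all(cr$rate[cr$type != "G>A"] == 0))
  # sum over preceding bases equals the count of events with context
  expect_equal(sum(cr$count[cr$type == "G>A"]), 3)
  expect_error(per_type_context_rates(ev, dinuc * 0, tx),
               class = "txerror_parameter_error")
})

test_that("context multipliers are recovered as conditional rate ratios", {
  tx <- generate_transcriptome(4, c(900, 1100), 0.5, seed = 17)
  m <- error_model(c("G>A" = 4e-4), context_multipliers = c("C:G>A" = 5),
                   seq_error_rate = 0.01)
  ms <- simulate_molecules(tx, 400, m, seed = 18)
  reads <- build_library(ms, m, seed = 19)
  calls <- call_errors(reads, tx)
  cr <- per_type_context_rates(calls$events, calls$denominator$dinuc, tx)
  rc <- cr[cr$preceding == "C" & cr$type == "G>A", ]
  ra <- cr[cr$preceding == "A" & cr$type == "G>A", ]
  expect_gt(rc$count, 20)
  ratio <- rc$rate / ra$rate
  # log-scale CI on the ratio of two Poisson rates
  se <- sqrt(1 / rc$count + 1 / ra$count)
  expect_lt(abs(log(ratio) - log(5)), 3 * se)
})
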