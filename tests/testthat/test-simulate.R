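test_that("zero-rate simulation leaves molecules identical to templates", {
  tx <- generate_transcriptome(5, c(300, 500), 0.5, seed = 1)
  ms <- simulate_molecules(tx, 50, error_model(), seed = 2)
  expect_equal(nrow(ms$ledger), 0L)
  tmpl <- molecule_sequences(ms)
  for (i in seq_along(ms$molecules)) {
    t <- ms$molecules[[i]]$transcript_id
    expect_identical(tmpl[i], tx$sequence[tx$id == t])
  }
  expect_equal(sum(ms$base_counts),
               sum(vapply(ms$molecules, function(m) length(m$seq), integer(1))))
})

test_that("injected counts follow the binomial expectation", {
  tx <- generate_transcriptome(1, c(1000, 1000), 0.5, seed = 3)
  m <- error_model(c("G>A" = 1e-3))
  ms <- simulate_molecules(tx, 400, m, seed = 4)
  n_g <- ms$base_counts[["G"]]
  expect_gt(n_g, 5e4)
  n_ga <- sum(ms$ledger$type == "sub" & ms$ledger$from_base == "G" &
                ms$ledger$to_base == "A")
  expect_equal(nrow(ms$ledger), n_ga) # only G>A was injected
  sd_exp <- sqrt(n_g * 1e-3)
  expect_lt(abs(n_ga - n_g * 1e-3), 4 * sd_exp)
})

test_that("context multipliers raise the conditional rate", {
  tx <- generate_transcriptome(2, c(2000, 2000), 0.5, seed = 5)
  m <- error_model(c("G>A" = 1e-3), context_multipliers = c("C:G>A" = 5))
  ms <- simulate_molecules(tx, 400, m, seed = 6)
  led <- ms$ledger
  # classify each event by the reference base preceding it
  codes <- lapply(tx$sequence, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  names(codes) <- tx$id
  prev <- vapply(seq_len(nrow(led)), function(i) {
    if (led$position[i] == 0) return(NA_character_)
    codes[[led$transcript_id[i]]][led$position[i]]
  }, character(1))
  # site counts by preceding base
  sites_c <- 0; sites_other <- 0
  for (t in tx$id) {
    v <- codes[[t]]
    g <- which(v == "G")[-1]
    pc <- sum(v[g - 1] == "C")
    sites_c <- sites_c + pc
    sites_other <- sites_other + length(g) - pc
  }
  n_mol <- sum(vapply(ms$molecules, function(x) 1L, integer(1)))
  rate_c <- sum(prev == "C", na.rm = TRUE) / (sites_c * n_mol)
  rate_other <- sum(prev != "C", na.rm = TRUE) / (sites_other * n_mol)
  expect_gt(rate_c / rate_other, 3)
  expect_lt(rate_c / rate_other, 8)
})

test_that("ledger records match the reference at their positions", {
  tx <- generate_transcriptome(5, c(500, 800), 0.5, seed = 7)
  ms <- simulate_molecules(tx, 300, default_error_model(), seed = 8)
  led <- ms$ledger
  expect_gt(nrow(led), 10)
  for (i in seq_len(nrow(led))) {
    refb <- substr(tx$sequence[tx$id == led$transcript_id[i]],
                   led$position[i] + 1, led$position[i] + 1)
    expect_identical(led$from_base[i], refb)
  }
  expect_true(all(led$type %in% c("sub", "ins", "del")))
  subs <- led[led$type == "sub", ]
  expect_false(any(subs$from_base == subs$to_base))
})

test_that("indels shift molecule coordinates consistently", {
  tx <- tiny_tx(list(random_dna(400, seed = 9)))
  m <- error_model(ins_rate = 2e-3, del_rate = 2e-3)
  ms <- simulate_molecules(tx, 50, m, seed = 10)
  led <- ms$ledger
  expect_gt(nrow(led), 10)
  for (mol in ms$molecules) {
    lm <- led[led$molecule_id == mol$id, ]
    d <- sum(lm$type == "ins") - sum(lm$type == "del")
    expect_equal(length(mol$seq), 400L + d)
    if (!is.null(mol$refpos)) {
      # non-inserted bases carry their template identity unless substituted
      keep <- !is.na(mol$refpos) &
        !(mol$refpos %in% lm$position[lm$type == "sub"])
      tmpl <- match(strsplit(tx$sequence, "", fixed = TRUE)[[1]],
                    c("A", "C", "G", "T"))
      expect_equal(mol$seq[keep], tmpl[mol$refpos[keep] + 1L])
    }
  }
})

test_that("excessive total rates and bad inputs are rejected", {
  tx <- generate_transcriptome(2, c(300, 400), 0.5, seed = 11)
  too_hot <- error_model(stats::setNames(rep(0.1, 12), sub_types()),
                         ins_rate = 0.1, del_rate = 0.1,
                         context_multipliers = c("A:A>C" = 5, "C:A>C" = 5,
                                                 "G:A>C" = 5, "T:A>C" = 5))
  expect_error(simulate_molecules(tx, 10, too_hot, seed = 1),
               class = "txerror_parameter_error")
  expect_error(simulate_molecules(tx, 0, error_model(), seed = 1),
               class = "txerror_parameter_error")
})

test_that("transcripts are drawn proportional to expression weight", {
  tx <- tiny_tx(list(random_dna(300, seed = 12), random_dna(300, seed = 13)),
                weights = c(9, 1))
  ms <- simulate_molecules(tx, 2000, error_model(), seed = 14)
  picks <- vapply(ms$molecules, function(m) m$transcript_id, character(1))
  frac <- mean(picks == "t01")
  expect_lt(abs(frac - 0.9), 0.03)
})
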