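make_cf <- function(seq_str, period = nchar(seq_str)) {
  codes <- match(strsplit(seq_str, "", fixed = TRUE)[[1]], c("A","C","G","T"))
  structure(list(sequence = seq_str, called = !is.na(codes), codes = codes,
                 period = period), class = "consensus_fragment")
}

test_that("a consensus identical to a reference window maps cleanly", {
  tx <- generate_transcriptome(3, c(500, 700), 0.5, seed = 1)
  window <- substr(tx$sequence[2], 101, 190)
  ev <- map_and_call(make_cf(window), tx)
  expect_equal(nrow(ev), 0L)
  expect_identical(attr(ev, "status"), "ok")
  den <- attr(ev, "denominator")
  expect_equal(den$N, 90)
  expect_equal(unname(den$N_b[c("A","C","G","T")]),
               as.numeric(table(factor(strsplit(window, "")[[1]],
                                       levels = c("A","C","G","T")))))
  expect_equal(sum(den$coverage[[2]]), 90)
})

test_that("a single mismatch yields exactly one substitution event", {
  tx <- generate_transcriptome(3, c(500, 700), 0.5, seed = 2)
  window <- substr(tx$sequence[1], 51, 140)
  pos <- 30L
  ref <- substr(window, pos, pos)
  alt <- setdiff(c("A","C","G","T"), ref)[1]
  mut <- paste0(substr(window, 1, pos - 1), alt,
                substr(window, pos + 1, nchar(window)))
  ev <- map_and_call(make_cf(mut), tx)
  expect_equal(nrow(ev), 1L)
  expect_identical(ev$type, "sub")
  expect_identical(ev$ref, ref)
  expect_identical(ev$obs, alt)
  expect_equal(ev$position, 50 + pos - 1) # 0-based transcript coordinate
  expect_identical(ev$transcript_id, tx$id[1])
})

test_that("every rotation of a fragment maps back to the same window", {
  tx <- generate_transcriptome(2, c(600, 800), 0.5, seed = 3)
  window <- substr(tx$sequence[1], 201, 290)
  for (r in c(0L, 1L, 10L, 45L, 60L, 89L)) {
    rot <- paste0(substr(window, r + 1, 90), substr(window, 1, r))
    ev <- map_and_call(make_cf(rot), tx)
    expect_identical(attr(ev, "status"), "ok")
    expect_equal(nrow(ev), 0L)
    expect_equal(sum(attr(ev, "denominator")$coverage[[1]]), 90)
    expect_equal(which(attr(ev, "denominator")$coverage[[1]] > 0), 201:290)
  }
})

test_that("fragments matching two loci equally are discarded as ambiguous", {
  dup <- random_dna(120, seed = 4)
  tx <- tiny_tx(list(paste0(random_dna(200, seed = 5), dup,
                            random_dna(200, seed = 6)),
                     paste0(random_dna(150, seed = 7), dup,
                            random_dna(250, seed = 8))))
  frag <- substr(dup, 11, 100)
  ev <- map_and_call(make_cf(frag), tx)
  expect_identical(attr(ev, "status"), "ambiguous")
  expect_equal(nrow(ev), 0L)
  expect_equal(attr(ev, "denominator")$N, 0)
})

test_that("single-base indels are recovered at the right coordinate", {
  tx <- generate_transcriptome(2, c(600, 800), 0.5, seed = 9)
  window <- substr(tx$sequence[1], 101, 195) # 95 bases
  # deletion of window position 40 (transcript 0-based position 139)
  del <- paste0(substr(window, 1, 39), substr(window, 41, 95))
  ev <- map_and_call(make_cf(del), tx)
  expect_identical(attr(ev, "status"), "ok")
  expect_equal(nrow(ev), 1L)
  expect_identical(ev$type, "del")
  expect_equal(ev$position, 139)
  # insertion between window positions 50 and 51, choosing a base unlike
  # both neighbors so the gap coordinate is unambiguous
  ins_base <- setdiff(c("A", "C", "G", "T"),
                      c(substr(window, 50, 50), substr(window, 51, 51)))[1]
  ins <- paste0(substr(window, 1, 50), ins_base, substr(window, 51, 94))
  ev2 <- map_and_call(make_cf(ins), tx)
  expect_identical(attr(ev2, "status"), "ok")
  expect_equal(nrow(ev2), 1L)
  expect_identical(ev2$type, "ins")
  expect_identical(ev2$obs, ins_base)
  expect_equal(ev2$position, 150) # 0-based position immediately 3' of the gap
})

test_that("noiseless end-to-end calls match the truth ledger exactly", {
  # with no sequencing error and substitutions only, every fragment is
  # accepted, the denominator equals the brute-force provenance recount,
  # and the called event set equals the sequenced truth exactly
  tx <- generate_transcriptome(6, c(600, 900), 0.5, seed = 10)
  m <- error_model(stats::setNames(rep(3e-4, 12), sub_types()))
  ms <- simulate_molecules(tx, 150, m, seed = 11)
  reads <- build_library(ms, m, seed = 12, rotate = FALSE)
  calls <- call_errors(reads, tx)
  expect_equal(unname(calls$counts["n_used"]), nrow(reads$seq))
  expect_equal(unname(calls$counts["unmapped"]), 0L)
  # denominator recount from provenance (junction-ambiguous fragment-edge
  # error positions may be masked, at most one per ledger event)
  expect_lte(calls$denominator$N, sum(reads$provenance$frag_len))
  expect_gte(calls$denominator$N,
             sum(reads$provenance$frag_len) - nrow(ms$ledger))
  expect_equal(sum(unlist(calls$denominator$coverage)), calls$denominator$N)
  # expected events: ledger substitutions inside any sequenced fragment
  prov <- reads$provenance
  led <- ms$ledger
  ref_codes <- lapply(tx$sequence, function(s) strsplit(s, "", TRUE)[[1]])
  names(ref_codes) <- tx$id
  # an event is only guaranteed recoverable if no equal-scoring junction
  # alternative exists: flipping the fragment segment containing it by
  # +/- one period must cost strictly more mismatches than it saves
  unambiguous <- function(tid, w, lm, f) {
    offsets <- lm$position
    R <- ref_codes[[tid]]
    p <- length(w)
    consW <- R[w + 1]
    consW[match(offsets, w)] <- lm$to_base
    ok <- TRUE
    tail_idx <- which(w >= f)
    alt <- w[tail_idx] - p + 1
    if (all(alt >= 1)) {
      mm <- sum(consW[tail_idx] != R[alt])
      if (mm <= sum(offsets >= f)) ok <- FALSE
    }
    head_idx <- which(w <= f)
    alt <- w[head_idx] + p + 1
    if (all(alt <= length(R))) {
      mm <- sum(consW[head_idx] != R[alt])
      if (mm <= sum(offsets <= f)) ok <- FALSE
    }
    ok
  }
  expected_core <- character(0) # unambiguous interior events: must be found
  expected_all <- character(0)  # ambiguous ones may be masked
  for (i in seq_len(nrow(prov))) {
    mol <- ms$molecules[[prov$molecule[i]]]
    w <- (prov$frag_start[i]:(prov$frag_start[i] + prov$frag_len[i] - 1)) - 1L
    lm <- led[led$molecule_id == mol$id & led$position %in% w, ]
    if (nrow(lm) > 0) {
      keys <- paste(lm$transcript_id, lm$position, lm$to_base)
      expected_all <- c(expected_all, keys)
      core <- vapply(seq_len(nrow(lm)), function(r)
        !(lm$position[r] %in% c(w[1], w[length(w)])) &&
          unambiguous(lm$transcript_id[r], w, lm, lm$position[r]),
        logical(1))
      expected_core <- c(expected_core, keys[core])
    }
  }
  got <- paste(calls$events$transcript_id, calls$events$position,
               calls$events$obs)
  expect_true(all(expected_core %in% got))
  expect_true(all(got %in% expected_all))
  expect_gt(length(unique(expected_core)), 10) # the check is not vacuous
})

test_that("rotated noiseless libraries recover nearly all interior truth", {
  # with random rotations a small fraction of events can fall in a
  # junction-tied segment and be masked as coordinate-ambiguous; everything
  # that is called must still be a real injected error
  tx <- generate_transcriptome(6, c(600, 900), 0.5, seed = 20)
  m <- error_model(stats::setNames(rep(3e-4, 12), sub_types()))
  ms <- simulate_molecules(tx, 150, m, seed = 21)
  reads <- build_library(ms, m, seed = 22)
  calls <- call_errors(reads, tx)
  prov <- reads$provenance
  led <- ms$ledger
  expected_core <- character(0); expected_all <- character(0)
  for (i in seq_len(nrow(prov))) {
    mol <- ms$molecules[[prov$molecule[i]]]
    w <- (prov$frag_start[i]:(prov$frag_start[i] + prov$frag_len[i] - 1)) - 1L
    lm <- led[led$molecule_id == mol$id & led$position %in% w, ]
    if (nrow(lm) > 0) {
      keys <- paste(lm$transcript_id, lm$position, lm$to_base)
      expected_all <- c(expected_all, keys)
      expected_core <- c(expected_core,
                         keys[!(lm$position %in% c(w[1], w[length(w)]))])
    }
  }
  got <- paste(calls$events$transcript_id, calls$events$position,
               calls$events$obs)
  expect_true(all(got %in% expected_all)) # no false positives, ever
  expect_gte(mean(unique(expected_core) %in% got), 0.9)
})

test_that("error calling is deterministic", {
  tx <- generate_transcriptome(3, c(500, 700), 0.5, seed = 13)
  m <- default_error_model()
  ms <- simulate_molecules(tx, 60, m, seed = 14)
  reads <- build_library(ms, m, seed = 15)
  c1 <- call_errors(reads, tx)
  c2 <- call_errors(reads, tx)
  expect_identical(c1$events, c2$events)
  expect_identical(c1$denominator$N_b, c2$denominator$N_b)
})

test_that("empty transcriptomes are rejected", {
  expect_error(map_and_call(make_cf(random_dna(90, seed = 16)),
                            tibble::tibble(id = character(0),
                                           sequence = character(0),
                                           weight = numeric(0))),
               class = "txerror_parameter_error")
})
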