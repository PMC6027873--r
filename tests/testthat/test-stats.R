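test_that("exact Mann-Whitney matches the null-distribution oracle", {
  # randomized tie-free battery across all small group sizes
  set.seed(1)
  for (rep in 1:40) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    got <- mann_whitney_exact(x, y)
    exp <- oracle_mw_pwilcox(x, y)
    expect_equal(got$U, exp$U)
    expect_equal(got$p.value, exp$p, tolerance = 1e-12)
  }
})

test_that("complete separation at n = 8 gives p = 2/12870", {
  got <- mann_whitney_exact(1:8, 9:16)
  expect_equal(got$U, 0)
  expect_equal(got$p.value, 2 / 12870, tolerance = 1e-12)
})

test_that("ties are handled by direct enumeration", {
  set.seed(2)
  for (rep in 1:10) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- sample(1:3, nx, replace = TRUE)
    y <- sample(1:3, ny, replace = TRUE)
    got <- mann_whitney_exact(x, y)
    exp <- oracle_mw_enum(x, y)
    expect_equal(got$U, exp$U)
    expect_equal(got$p.value, exp$p, tolerance = 1e-12)
  }
  # identical multisets are perfectly exchangeable
  expect_equal(mann_whitney_exact(c(1, 2, 2), c(2, 1, 2))$p.value, 1)
  expect_error(mann_whitney_exact(numeric(0), 1),
               class = "txerror_parameter_error")
})

test_that("the t-test matches the textbook formulas", {
  set.seed(3)
  for (rep in 1:20) {
    x <- rnorm(sample(2:10, 1)); y <- rnorm(sample(2:10, 1), mean = 0.5)
    got <- t_test_unpaired(x, y)
    exp <- oracle_t_formula(x, y, pooled = TRUE)
    expect_equal(got$t, exp$t, tolerance = 1e-12)
    expect_equal(got$p.value, exp$p, tolerance = 1e-12)
    gw <- t_test_unpaired(x, y, var_equal = FALSE)
    ew <- oracle_t_formula(x, y, pooled = FALSE)
    expect_equal(gw$t, ew$t, tolerance = 1e-12)
    expect_equal(gw$p.value, ew$p, tolerance = 1e-12)
  }
})

test_that("degenerate-variance t-tests are resolved explicitly", {
  same <- t_test_unpaired(c(1, 1), c(1, 1))
  expect_equal(same$p.value, 1)
  expect_true(same$degenerate)
  diff <- t_test_unpaired(c(0, 0), c(1, 1))
  expect_equal(diff$p.value, 0)
  expect_true(diff$degenerate)
  expect_error(t_test_unpaired(1, c(1, 2)), class = "txerror_parameter_error")
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(0, 5, 5, 0), 2)), 2 / 252,
               tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), 1) # zero margin
  set.seed(4)
  for (rep in 1:60) {
    m <- matrix(rpois(4, sample(1:12, 1)), 2)
    if (sum(m) > 50) next
    expect_equal(fisher_exact_2x2(m), oracle_fisher_enum(m),
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)),
               class = "txerror_parameter_error")
})

test_that("Benjamini-Hochberg equals the hand step-up rule", {
  got <- benjamini_hochberg(c(0.001, 0.01, 0.02, 0.04, 0.2), fdr = 0.05)
  expect_identical(got$reject, c(TRUE, TRUE, TRUE, TRUE, FALSE))

  all1 <- benjamini_hochberg(rep(1, 6))
  expect_false(any(all1$reject))
  expect_true(all(all1$q == 1))

  expect_true(benjamini_hochberg(0.04)$reject)   # m = 1 identity
  expect_false(benjamini_hochberg(0.06)$reject)

  set.seed(5)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    got <- benjamini_hochberg(p, fdr = 0.05)
    exp <- oracle_bh_stepup(p, fdr = 0.05)
    expect_identical(got$reject, exp$reject)
    expect_equal(got$q, exp$q, tolerance = 1e-12)
    # q-values are monotone along the sorted p-values
    expect_true(all(diff(got$q[order(p)]) >= -1e-12))
    # BH rejects at least everything Bonferroni rejects
    bonf <- p <= 0.05 / length(p)
    expect_true(all(got$reject[bonf]))
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)),
               class = "txerror_parameter_error")
})

test_that("grouping by gene splits the design correctly", {
  design <- study_design(replicates = 2)
  rt <- tibble::tibble(sample_id = design$sample_id,
                       R = seq_len(nrow(design)) * 1e-5)
  for (g in c("greA", "greB", "dksA")) {
    gr <- group_by_gene(rt, design, g)
    expect_length(gr$plus, 8L)
    expect_length(gr$minus, 8L)
    expect_setequal(c(gr$samples_plus, gr$samples_minus), design$sample_id)
  }
  gr <- group_by_gene(rt, design, "greA")
  expect_setequal(unique(sub("_r[12]$", "", gr$samples_plus)),
                  c("WT", "dgreB", "ddksA", "dgreBdksA"))
  d1 <- study_design(replicates = 1)
  rt1 <- tibble::tibble(sample_id = d1$sample_id, R = runif(8))
  expect_length(group_by_gene(rt1, d1, "dksA")$plus, 4L)
  expect_error(group_by_gene(rt, design, "rpoB"),
               class = "txerror_parameter_error")
})
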