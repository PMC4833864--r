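test_that("pearson_correlation matches the closed form and handles exact relations", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(3, 2, 1)), -1)
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  expect_equal(pearson_correlation(x, y), oracle_pearson(x, y))
  expect_equal(pearson_correlation(x, y), 0.8)
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10)
    expect_equal(pearson_correlation(a, b), oracle_pearson(a, b))
  }
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson_correlation(c(1, 2), c(1, 2)), "length")
})

test_that("scale_row standardizes with the n-1 denominator and is affine-equivariant", {
  expect_equal(scale_row(c(5, 5, 7, 7)),
               c(-sqrt(3) / 2, -sqrt(3) / 2, sqrt(3) / 2, sqrt(3) / 2))
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(15)
    s <- scale_row(x)
    expect_equal(mean(s), 0)
    expect_equal(sd(s), 1)
    a <- runif(1, -3, 3); while (abs(a) < 0.1) a <- runif(1, -3, 3)
    expect_equal(scale_row(a * x + 2), sign(a) * scale_row(x))
  }
  expect_error(scale_row(rep(4, 6)), "variance")
})

test_that("rescale_to restores requested moments and round-trips", {
  expect_equal(rescale_to(c(1, 2, 3), 10, 2), c(8, 10, 12))
  set.seed(31)
  m <- rnorm(12, mean = 5, sd = 3)
  expect_equal(rescale_to(scale_row(m), mean(m), sd(m)), m)
  expect_equal(rescale_to(m, 0, 1), scale_row(m))
  out <- rescale_to(rnorm(9), -2.5, 0.7)
  expect_equal(mean(out), -2.5)
  expect_equal(sd(out), 0.7)
  expect_error(rescale_to(c(1, 2, 3), 0, 0), "target_sd")
})

test_that("first_pc_rows handles degenerate two-row structures and k = 1", {
  r <- c(2, 4, 1, 7, 3, 5)
  same <- first_pc_rows(rbind(r, r), reference = r)
  expect_equal(cosine(same, scale_row(r)), 1, tolerance = 1e-12)
  opp <- first_pc_rows(rbind(r, -r), reference = r)
  expect_equal(abs(cosine(opp, scale_row(r))), 1, tolerance = 1e-12)
  expect_gt(cor(opp, r), 0)
  single <- first_pc_rows(r, reference = -r)
  expect_equal(single, -scale_row(r))
})

test_that("first_pc_rows agrees with dense eigendecomposition of the correlation matrix", {
  set.seed(41)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    n <- sample(5:15, 1)
    rows <- random_matrix(k, n)
    ref <- rows[1, ]
    got <- first_pc_rows(rows, reference = ref)
    want <- oracle_first_pc(rows, reference = ref)
    expect_equal(abs(cosine(got, want)), 1, tolerance = 1e-9)
    expect_gte(cor(got, want), 0)
  }
})

test_that("adjust_row applies the three gates and always restores row moments", {
  m <- c(1, 2, 3, 5)

  # identical rows: rho = 1, scenario 3 is a fixed point
  res <- adjust_row(m, m)
  expect_equal(res$scenario, "scenario3")
  expect_equal(res$row, m)

  # anti-correlated partner: gate (a) leaves the row untouched
  res <- adjust_row(m, rev(m))
  expect_equal(res$scenario, "scenario1")
  expect_identical(res$row, m)

  # moderate correlation: correlation-weighted sum, verified step by step
  c2 <- c(1, 5, 2, 4)
  rho <- oracle_pearson(c2, m)
  expect_gt(rho, 0); expect_lte(rho, 0.5)
  res <- adjust_row(m, c2)
  expect_equal(res$scenario, "scenario2")
  expect_equal(res$rho, rho)
  v <- oracle_scale(m) + rho * oracle_scale(c2)
  expect_equal(res$row, oracle_scale(v) * sd(m) + mean(m))

  # high correlation: first PC of the two standardized rows
  c3 <- c(2, 1, 4, 5)
  rho3 <- oracle_pearson(c3, m)
  expect_gt(rho3, 0.5)
  res <- adjust_row(m, c3)
  expect_equal(res$scenario, "scenario3")
  v3 <- oracle_first_pc(rbind(m, c3), reference = m)
  expect_equal(res$row, oracle_scale(v3) * sd(m) + mean(m))

  # degenerate partner: skipped, row passed through
  res <- adjust_row(m, rep(1, 4))
  expect_equal(res$scenario, "skipped")
  expect_identical(res$row, m)
  expect_true(is.na(res$rho))
})

test_that("scenario-2 output tracks the partner more closely as rho grows", {
  set.seed(51)
  m <- rnorm(30)
  rhos <- seq(0.05, 0.45, by = 0.05)
  cors <- vapply(rhos, function(r) {
    c_r <- pair_with_correlation(m, r)
    res <- adjust_row(m, c_r)
    expect_equal(res$scenario, "scenario2")
    cor(res$row, scale_row(c_r))
  }, numeric(1))
  expect_true(all(diff(cors) >= -1e-12))
})

test_that("adjust_matrix conserves moments, gates exhaustively and matches a row loop", {
  set.seed(61)
  main <- random_matrix(50, 8)
  assoc <- main + matrix(rnorm(50 * 8, sd = 1.2), 50, 8)
  dimnames(assoc) <- dimnames(main)
  res <- adjust_matrix(main, assoc)

  expect_identical(dimnames(res$adjusted), dimnames(main))
  expect_true(all(res$scenario %in%
                    c("skipped", "scenario1", "scenario2", "scenario3")))

  # independent per-row re-evaluation of the gating rule
  want <- vapply(seq_len(50), function(i) {
    r <- oracle_pearson(assoc[i, ], main[i, ])
    if (r <= 0) "scenario1" else if (r <= 0.5) "scenario2" else "scenario3"
  }, character(1))
  expect_equal(unname(res$scenario), want)

  for (i in which(res$scenario != "skipped")) {
    expect_equal(mean(res$adjusted[i, ]), mean(main[i, ]), tolerance = 1e-9)
    expect_equal(sd(res$adjusted[i, ]), sd(main[i, ]), tolerance = 1e-9)
  }
  kept <- res$scenario %in% c("skipped", "scenario1")
  expect_identical(res$adjusted[kept, ], main[kept, ])
})

test_that("adjust_matrix honours the skip mask and rejects sample mismatches", {
  main <- random_matrix(10, 6, seed = 71)
  res <- adjust_matrix(main, main, skip = rep(TRUE, 10))
  expect_identical(res$adjusted, main)
  expect_true(all(res$scenario == "skipped"))

  shuffled <- main[, c(2, 1, 3:6)]
  expect_error(adjust_matrix(main, shuffled), "sample order mismatch.*s002")
})

test_that("adjusting both inputs with permuted sample columns permutes the output", {
  set.seed(81)
  main <- random_matrix(20, 10)
  assoc <- main + matrix(rnorm(200, sd = 0.8), 20, 10)
  dimnames(assoc) <- dimnames(main)
  perm <- sample(10)
  base <- adjust_matrix(main, assoc)
  permuted <- adjust_matrix(main[, perm], assoc[, perm])
  expect_equal(permuted$adjusted, base$adjusted[, perm])
  expect_equal(permuted$scenario, base$scenario)
})

test_that("select_cutoff2 hits the requested scenario-3 fraction", {
  rho <- seq(0.01, 0.99, by = 0.01)
  cut <- select_cutoff2(rho, 1 / 3)
  # sort-and-count brute force: exactly 33 of 99 values strictly exceed it
  expect_equal(sum(rho > cut), 33)
  expect_equal(cut, unname(quantile(rho, 2 / 3)))

  expect_equal(select_cutoff2(rep(0.4, 10)), 0.4)
  expect_equal(sum(rep(0.4, 10) > select_cutoff2(rep(0.4, 10))), 0)

  # as the target fraction approaches one, the cutoff approaches the minimum
  expect_equal(select_cutoff2(rho, 0.999), min(rho), tolerance = 1e-2)
  expect_error(select_cutoff2(rep(NA_real_, 5)), "finite")
  expect_error(select_cutoff2(rho, 1.2), "target_fraction")
})
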