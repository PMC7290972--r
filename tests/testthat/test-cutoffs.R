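test_that("sentinel augmentation applies the ±1 rule literally", {
  expect_equal(augment_with_sentinels(c(2.0, 5.0, 3.0)), c(1, 2, 3, 5, 6))
  expect_equal(augment_with_sentinels(4.2), c(3.2, 4.2, 5.2))
  expect_equal(augment_with_sentinels(c(2, 2)), c(1, 2, 2, 3))
  expect_error(augment_with_sentinels(numeric(0)), class = "fgrms_error_validation")
})

test_that("candidate cut-offs are neighbour midpoints", {
  expect_equal(candidate_cutoffs(c(1, 2, 3, 5, 6)), c(1.5, 2.5, 4.0, 5.5))
  expect_equal(candidate_cutoffs(c(0, 10)), 5.0)
  expect_equal(candidate_cutoffs(c(1, 2, 2, 3)), c(1.5, 2, 2.5))
  expect_error(candidate_cutoffs(c(3, 1, 2)), class = "fgrms_error_validation")
})

test_that("youden_scan finds the separating threshold and honours ties", {
  values <- c(1, 2, 3, 10, 11, 12)
  labels <- rep(c("CTRL", "FGR"), each = 3)
  res <- youden_scan(values, labels)
  expect_equal(res$best_cutoff, 6.5) # midpoint of 3 and 10
  expect_equal(res$j_max, 1.0)
  expect_equal(res$sensitivity, 1.0)
  expect_equal(res$specificity, 1.0)
  expect_equal(nrow(res$scan), length(values) + 1L)

  # Identical distributions carry no information.
  same <- youden_scan(rep(5, 6), rep(c("CTRL", "FGR"), each = 3))
  expect_equal(same$j_max, 0.0)

  # Overlapping groups: every candidate's J agrees with direct computation,
  # and the optimum agrees with the brute-force oracle.
  v <- c(1, 2, 3, 4.5, 4, 6, 7, 8)
  l <- rep(c("CTRL", "FGR"), each = 4)
  res2 <- youden_scan(v, l)
  direct <- vapply(res2$scan$cutoff, j_at_cutoff, numeric(1),
                   values = v, labels = l)
  expect_equal(res2$scan$j, direct)
  expect_equal(res2$j_max, brute_force_youden(v, l)$j_max)

  expect_error(youden_scan(1:4, rep("FGR", 4)), class = "fgrms_error_validation")
})

test_that("youden_scan matches the brute-force oracle on random labelled lists", {
  withr::with_seed(2024, {
    for (i in 1:200) {
      n_pos <- sample(2:25, 1)
      n_neg <- sample(2:25, 1)
      shift <- runif(1, 0, 3)
      values <- c(round(rnorm(n_neg), 2), round(rnorm(n_pos, shift), 2))
      labels <- rep(c("CTRL", "FGR"), c(n_neg, n_pos))
      res <- youden_scan(values, labels)
      oracle <- brute_force_youden(values, labels)
      expect_equal(res$j_max, oracle$j_max)
      expect_equal(j_at_cutoff(res$best_cutoff, values, labels), res$j_max)
      expect_true(all(res$scan$j >= -1 & res$scan$j <= 1))
      expect_gte(res$j_max, 0)
    }
  })
})

test_that("the trained classification is invariant to monotone transforms", {
  withr::with_seed(31, {
    values <- c(rnorm(12, 0), rnorm(12, 1.5))
    labels <- rep(c("CTRL", "FGR"), each = 12)
    res <- youden_scan(values, labels)
    res_t <- youden_scan(exp(values), labels)
    expect_equal(res_t$j_max, res$j_max)
    expect_equal(exp(values) > res_t$best_cutoff, values > res$best_cutoff)
  })
})

test_that("train_cutoff_set separates a separable set perfectly and is deterministic", {
  q <- tibble::tibble(
    A = c(1, 2, 3, 10, 11, 12), B = c(2, 2.5, 3, 8, 9, 10),
    C = c(0.5, 1, 1.5, 5, 6, 7),
    cohort = rep(c("CTRL", "FGR"), each = 3)
  )
  cs <- train_cutoff_set(q, training_label = "O")
  expect_s3_class(cs, "cutoff_set")
  expect_true(all(cs$table$sensitivity == 1))
  expect_true(all(cs$table$specificity == 1))
  expect_true(all(cs$table$j_max == 1))
  expect_identical(tidy(train_cutoff_set(q, training_label = "O")), tidy(cs))
  expect_error(train_cutoff_set(q[c("A", "B", "cohort")]),
               "C", class = "fgrms_error_validation")
})

test_that("permuted labels drive Jmax towards zero", {
  withr::with_seed(17, {
    q <- tibble::tibble(
      A = exp(rnorm(28, c(rep(0, 14), rep(1.5, 14)), 0.3)),
      B = exp(rnorm(28, c(rep(0, 14), rep(1.5, 14)), 0.3)),
      C = exp(rnorm(28, c(rep(0, 14), rep(1.0, 14)), 0.3)),
      cohort = rep(c("CTRL", "FGR"), each = 14)
    )
    jmax_perm <- replicate(20, {
      qp <- q
      qp$cohort <- sample(qp$cohort)
      max(train_cutoff_set(qp)$table$j_max)
    })
    # With n = 14 + 14 and no signal, Jmax stays small for nearly all draws.
    expect_lte(stats::quantile(jmax_perm, 0.95), 0.45)
    expect_lt(median(jmax_perm), 0.4)
  })
})

test_that("combining cut-off sets takes element-wise min/max and is symmetric", {
  o <- cutoff_set(A = 4.2, B = 5.0, C = 4.0, training_label = "O")
  w <- cutoff_set(A = 3.4, B = 7.0, C = 5.1, training_label = "W")
  dual <- combine_cutoffs(o, w)
  expect_equal(dual$table$lower, c(3.4, 5.0, 4.0))
  expect_equal(dual$table$upper, c(4.2, 7.0, 5.1))
  expect_equal(tidy(combine_cutoffs(w, o)), tidy(dual))
  expect_error(combine_cutoffs(o, o), class = "fgrms_error_validation")
})

test_that("cut-offs survive a JSON round trip", {
  tmp <- withr::local_tempfile(fileext = ".json")
  dual <- cutoffs_paper_ow()
  write_cutoffs(dual, tmp)
  back <- read_cutoffs(tmp)
  expect_s3_class(back, "dual_cutoffs")
  expect_equal(back$table, dual$table)

  single <- cutoff_set(4.2, 5.0, 4.0, training_label = "O")
  write_cutoffs(single, tmp)
  back2 <- read_cutoffs(tmp)
  expect_s3_class(back2, "cutoff_set")
  expect_equal(back2$table$cutoff, single$table$cutoff)
})
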