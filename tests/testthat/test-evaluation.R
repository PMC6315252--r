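test_that("163 posts with 34 mismatches give the published error and accuracy", {
  n <- 163; n_err <- 34
  ids <- sprintf("p%03d", seq_len(n))
  manual <- stats::setNames(rep("science_and_health", n), ids)
  assigned <- rep("science_and_health", n)
  assigned[seq_len(n_err)] <- "anniversaries"
  a <- data.frame(post_id = ids, assigned_category = assigned,
                  stringsAsFactors = FALSE)
  r <- evaluate_assignments(a, manual)
  expect_equal(r$n_posts, 163)
  expect_equal(r$n_errors, 34)
  expect_equal(r$error_rate, 100 * 34 / 163)
  expect_equal(r$accuracy + r$error_rate, 100)
  # printed as 20.8% error / 79.2% accuracy (the source truncated 20.858)
  expect_lt(abs(r$error_rate - 20.8), 0.1)
  expect_lt(abs(r$accuracy - 79.2), 0.1)
})

test_that("perfect agreement yields 100% accuracy and a diagonal confusion matrix", {
  co <- generate_corpus(generator_config(40, seed = 2, cross_noise = 0))
  a <- classify_corpus(co, demo_dictionary())
  r <- evaluate_assignments(a, co)
  expect_equal(r$accuracy, 100)
  expect_equal(r$n_errors, 0)
  expect_equal(sum(r$confusion) - sum(diag(r$confusion)), 0)
  expect_true(all(is.na(r$per_category$pct_of_total_errors)))
})

test_that("confusion margins match label counts and errors are order-invariant", {
  set.seed(123)
  n <- 120
  cats <- letters[1:4]
  ids <- as.character(seq_len(n))
  manual <- stats::setNames(sample(cats, n, replace = TRUE), ids)
  a <- data.frame(post_id = ids,
                  assigned_category = sample(cats, n, replace = TRUE),
                  stringsAsFactors = FALSE)
  r <- evaluate_assignments(a, manual)
  expect_equal(as.vector(rowSums(r$confusion)),
               as.vector(table(factor(manual, levels = sort(cats)))))
  expect_equal(as.vector(colSums(r$confusion)),
               as.vector(table(factor(a$assigned_category,
                                      levels = sort(cats)))))
  expect_equal(r$n_errors, sum(r$confusion) - sum(diag(r$confusion)))
  perm <- sample(n)
  expect_equal(evaluate_assignments(a[perm, ], manual)$error_rate,
               r$error_rate)
})

test_that("random assignments over k categories sit at chance accuracy", {
  set.seed(7)
  k <- 4
  n <- 4000
  ids <- as.character(seq_len(n))
  manual <- stats::setNames(sample(letters[1:k], n, replace = TRUE), ids)
  a <- data.frame(post_id = ids,
                  assigned_category = sample(letters[1:k], n, replace = TRUE))
  r <- evaluate_assignments(a, manual)
  # binomial(4000, 1/4): 4 sigma is about 2.7 percentage points
  expect_lt(abs(r$accuracy - 100 / k), 3)
})

test_that("the per-category breakdown reports error shares as printed", {
  # a category holding 10 of 34 errors -> 29.4% of total errors
  n <- 163
  ids <- sprintf("p%03d", seq_len(n))
  manual <- stats::setNames(rep("x", n), ids)
  assigned <- rep("x", n)
  assigned[1:10] <- "anniversaries"    # 10 errors
  assigned[11:34] <- "solidarity"      # the other 24
  a <- data.frame(post_id = ids, assigned_category = assigned)
  b <- error_breakdown(evaluate_assignments(a, manual))
  expect_equal(b$pct_of_total_errors[b$category == "anniversaries"], 29.4)
  expect_equal(sum(b$n_errors), 34)
  expect_equal(b$n_assigned[b$category == "anniversaries"], 10)
})

test_that("rounded error shares sum to about 100 on random reports", {
  set.seed(9)
  for (rep_i in 1:5) {
    n <- 150
    ids <- as.character(seq_len(n))
    manual <- stats::setNames(sample(letters[1:5], n, replace = TRUE), ids)
    a <- data.frame(post_id = ids,
                    assigned_category = sample(letters[1:5], n,
                                               replace = TRUE))
    b <- error_breakdown(evaluate_assignments(a, manual))
    expect_lt(abs(sum(b$pct_of_total_errors) - 100), 0.3)
  }
})

test_that("a missing manual label is an error naming the post", {
  a <- data.frame(post_id = c("1", "2"), assigned_category = "x")
  expect_error(evaluate_assignments(a, c(`1` = "x")),
               "missing manual label.*2")
})
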