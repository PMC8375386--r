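test_that("split plans stratify, fix the test set, and keep slices disjoint", {
  sim <- strong_sim(seed = 3, n_cities = 3, samples_per_group = 10)
  index <- build_group_index(sim$meta)
  plan <- make_split_plan(index, n_reps = 5, seed = 8)
  all_ids <- sim$meta$sample_id
  # group of 10 -> 2 test; remainder 8 -> 2 validation / 6 train per rep
  test_by_group <- table(geotrace:::group_of(index, plan$test))
  expect_true(all(test_by_group == 2L))
  for (rep in plan$reps) {
    expect_length(intersect(plan$test, c(rep$train, rep$val)), 0L)
    expect_length(intersect(rep$train, rep$val), 0L)
    expect_setequal(c(plan$test, rep$train, rep$val), all_ids)
    val_by_group <- table(geotrace:::group_of(index, rep$val))
    expect_true(all(val_by_group == 2L))
  }
  plan2 <- make_split_plan(index, n_reps = 5, seed = 8)
  expect_identical(plan$test, plan2$test)
  expect_identical(plan$reps, plan2$reps)
})

test_that("a single-repetition plan is a single partition", {
  sim <- strong_sim(seed = 3, n_cities = 3, samples_per_group = 6)
  index <- build_group_index(sim$meta)
  plan <- make_split_plan(index, n_reps = 1, seed = 1)
  expect_length(plan$reps, 1L)
})

test_that("top-k error follows the vote-rank rules", {
  votes <- rbind(
    s1 = c(A = 60L, B = 40L, C = 0L),
    s2 = c(A = 100L, B = 0L, C = 0L),
    s3 = c(A = 50L, B = 50L, C = 0L)
  )
  tally <- manual_tally(votes, truth = c(s1 = "B", s2 = "A", s3 = "B"))
  # s1: truth holds the second rank -> top-1 wrong, top-2 right
  # s2: truth holds the top rank alone -> right under both
  # s3: tie at the top includes the truth -> right (generous), wrong (strict)
  expect_equal(topk_error(tally, 1), 1 / 3)
  expect_equal(topk_error(tally, 2), 0)
  expect_equal(topk_error(tally, 1, ties = "strict"), 2 / 3)
})

test_that("top-2 error never exceeds top-1 error over random tallies", {
  withr::with_seed(14, {
    for (i in 1:25) {
      n <- sample(3:12, 1)
      g <- sample(3:6, 1)
      votes <- matrix(
        as.integer(rmultinom(n, 100, runif(g))),
        ncol = g, byrow = TRUE,
        dimnames = list(sprintf("s%d", 1:n), LETTERS[1:g])
      )
      tally <- manual_tally(votes, setNames(
        sample(LETTERS[1:g], n, replace = TRUE), sprintf("s%d", 1:n)
      ))
      expect_lte(topk_error(tally, 2), topk_error(tally, 1))
    }
  })
})

test_that("overall error is the sample-weighted mean of per-group errors", {
  sim <- strong_sim(seed = 9, n_cities = 3, samples_per_group = 10,
                    effect = 0.5)
  fx <- normalized_from_sim(sim)
  plan <- make_split_plan(fx$index, n_reps = 3, seed = 2)
  tally <- run_protocol(fx$x, fx$index, plan,
    learner_spec("rf", n_trees = 200, seed = 4)
  )
  expect_true(all(tally$n_tested == plan$n_reps))
  pge <- per_group_error(tally, fx$index, 1)
  weighted <- sum(pge$error * pge$n_test) / sum(pge$n_test)
  expect_equal(weighted, topk_error(tally, 1))
})

test_that("a five-sample group with one miss shows error 0.2", {
  votes <- matrix(0L, 5, 2, dimnames = list(sprintf("g1_%d", 1:5), c("X_17", "Y_17")))
  votes[, 1] <- 10L
  votes[5, ] <- c(0L, 10L) # one sample voted into the wrong group
  meta <- tibble::tibble(
    sample_id = sprintf("g1_%d", 1:5), city = "X", year = 2017L
  )
  index <- build_group_index(meta)
  tally <- manual_tally(votes, setNames(rep("X_17", 5), rownames(votes)))
  pge <- per_group_error(tally, index, 1)
  expect_equal(pge$error[pge$group == "X_17"], 0.2)
})

test_that("year confusion counts same-city-different-year top votes", {
  classes <- c("X_16", "X_17", "Y_17")
  ids <- c("a", "b", "c", "d")
  votes <- matrix(0L, 4, 3, dimnames = list(ids, classes))
  votes["a", ] <- c(1L, 9L, 0L)  # truth X_16, voted X_17 -> confused
  votes["b", ] <- c(9L, 1L, 0L)  # truth X_16, correct
  votes["c", ] <- c(0L, 1L, 9L)  # truth X_17, voted Y_17 -> wrong city, no
  votes["d", ] <- c(0L, 0L, 10L) # truth Y_17, single-year city -> excluded
  meta <- tibble::tibble(
    sample_id = ids,
    city = c("X", "X", "X", "Y"),
    year = c(2016L, 2016L, 2017L, 2017L)
  )
  index <- build_group_index(meta)
  truth <- setNames(c("X_16", "X_16", "X_17", "Y_17"), ids)
  res <- year_confusion(manual_tally(votes, truth), index)
  expect_equal(res$count, 1L)
  expect_equal(res$denominator, 3L)

  # no multi-year city -> empty denominator
  meta1 <- tibble::tibble(sample_id = ids, city = c("X", "X", "Y", "Y"),
                          year = 2017L)
  res0 <- year_confusion(manual_tally(votes, truth), build_group_index(meta1))
  expect_equal(res0, list(count = 0L, denominator = 0L))
})

test_that("all three learners solve a perfectly separable problem", {
  sim <- strong_sim(seed = 7, n_cities = 3, samples_per_group = 10, effect = 4)
  fx <- normalized_from_sim(sim)
  plan <- make_split_plan(fx$index, n_reps = 2, seed = 5)
  for (method in c("rf", "svm", "mlp")) {
    spec <- learner_spec(method, n_trees = 300, epochs = 60, seed = 11)
    tally <- run_protocol(fx$x, fx$index, plan, spec)
    expect_equal(topk_error(tally, 1), 0, info = method)
    # every sample's true class received every vote
    truth_votes <- tally$votes[cbind(
      seq_len(nrow(tally$votes)), match(tally$truth, colnames(tally$votes))
    )]
    expect_true(all(truth_votes == plan$n_reps), info = method)
  }
})
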