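test_that("fold plans partition the data with balanced sizes", {
  plan <- make_fold_plan(20, dcv_spec(n_outer = 5, n_inner = 4, seed = 1))
  sizes <- table(plan[[1]]$outer)
  expect_equal(unname(as.integer(sizes)), rep(4L, 5))

  plan529 <- make_fold_plan(529, dcv_spec(seed = 2))
  expect_equal(sort(as.integer(table(plan529[[1]]$outer))),
               c(105L, 106L, 106L, 106L, 106L))

  # 5 x 4 scheme: 20 (training, stop) pairs per repetition
  n_pairs <- sum(vapply(plan529[[1]]$inner,
                        function(i) length(unique(i)), integer(1)))
  expect_equal(n_pairs, 20)
  expect_error(make_fold_plan(10, dcv_spec()), "too small")
})

test_that("every compound sits in exactly one outer fold per repetition and inner folds partition the complement", {
  spec <- dcv_spec(n_outer = 5, n_inner = 4, n_rep = 3, seed = 7)
  plan <- make_fold_plan(103, spec)
  for (r in seq_len(3)) {
    outer <- plan[[r]]$outer
    expect_equal(length(outer), 103)
    expect_setequal(unique(outer), 1:5)
    for (o in 1:5) {
      inner <- plan[[r]]$inner[[o]]
      rows <- as.integer(names(inner))
      expect_setequal(rows, which(outer != o))
      expect_true(all(abs(diff(as.integer(table(inner)))) <= 1))
    }
  }
  # repetitions are reshuffled independently
  expect_false(identical(plan[[1]]$outer, plan[[2]]$outer))
})

test_that("consolidation implements the cross-validation identities", {
  y <- c(1, 2, 3, 4)
  perfect <- tibble::tibble(row = 1:4, rep = 1, predicted = y)
  cv <- consolidate_cv(perfect, y)
  expect_equal(cv$PRESS, 0)
  expect_equal(cv$Q2, 1)
  expect_equal(cv$RMSEcv, 0)

  at_mean <- tibble::tibble(row = 1:4, rep = 1, predicted = rep(mean(y), 4))
  cv2 <- consolidate_cv(at_mean, y)
  expect_equal(cv2$Q2, 0)
  expect_equal(cv2$PRESS, cv2$SS)

  unit_err <- tibble::tibble(row = 1:4, rep = 1, predicted = y + 1)
  cv3 <- consolidate_cv(unit_err, y)
  expect_equal(cv3$PRESS, 4)
  expect_equal(cv3$RMSEcv, 1)

  # algebraic cross-check: Q2 = 1 - RMSEcv^2 * N / SS
  for (cvx in list(cv, cv2, cv3)) {
    expect_equal(cvx$Q2, 1 - cvx$RMSEcv^2 * cvx$N / cvx$SS)
  }

  expect_error(consolidate_cv(perfect, rep(2, 4)), "SS = 0")
  expect_error(consolidate_cv(perfect[1:3, ], y), "at least one")
})

test_that("double cross-validation recovers a clean linear fragment model", {
  ds <- generate_dataset(synthetic_spec(n_compounds = 200, noise_sd = 0,
                                        max_atoms = 6, levels = 1:2,
                                        seed = 23))
  dm <- filter_rare(build_descriptor_matrix(ds$compounds, max_atoms = 6,
                                            levels = 1:2))
  res <- run_double_cv(dm, ds$compounds$logbb, dcv = dcv_spec(seed = 3),
                       selection = list(method = "stepwise_pls", k = 30,
                                        score = "f_value"),
                       max_epochs = 400, patience = 20)
  expect_gte(res$cv$Q2, 0.9)
  expect_equal(length(res$ensemble$members), 20)

  # no member ever saw its own validation rows during training
  plan <- make_fold_plan(nrow(dm$counts), dcv_spec(seed = 3))
  for (m in res$ensemble$members) {
    val_rows <- which(plan[[m$rep]]$outer == m$outer)
    expect_length(intersect(m$train_rows, val_rows), 0)
    expect_length(intersect(m$stop_rows, val_rows), 0)
    expect_length(intersect(m$train_rows, m$stop_rows), 0)
  }
})

test_that("repetitions give one out-of-fold prediction per compound each", {
  ds <- generate_dataset(synthetic_spec(n_compounds = 60, noise_sd = 0.2,
                                        max_atoms = 4, levels = 1,
                                        seed = 31))
  dm <- filter_rare(build_descriptor_matrix(ds$compounds, max_atoms = 4,
                                            levels = 1), min_support = 3)
  res <- run_double_cv(dm, ds$compounds$logbb,
                       dcv = dcv_spec(n_rep = 2, seed = 5),
                       selection = list(method = "univariate", k = 10,
                                        score = "f_value"),
                       max_epochs = 60, patience = 10)
  tab <- table(res$cv$predictions$row, res$cv$predictions$rep)
  expect_true(all(tab == 1))
  expect_equal(ncol(tab), 2)
})

test_that("an identical seed reproduces the cross-validation result exactly", {
  ds <- generate_dataset(synthetic_spec(n_compounds = 60, noise_sd = 0.2,
                                        max_atoms = 4, levels = 1,
                                        seed = 37))
  dm <- filter_rare(build_descriptor_matrix(ds$compounds, max_atoms = 4,
                                            levels = 1), min_support = 3)
  run <- function() {
    run_double_cv(dm, ds$compounds$logbb, dcv = dcv_spec(seed = 11),
                  selection = list(method = "univariate", k = 8,
                                   score = "f_value"),
                  max_epochs = 50, patience = 10)$cv
  }
  cv1 <- run(); cv2 <- run()
  expect_identical(glance(cv1), glance(cv2))
})
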