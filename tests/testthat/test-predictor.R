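# counts vector for a simple carbon compound (used with fabricated ensembles)
carbon_counts <- function() stats::setNames(2L, "L1|A|C")

test_that("a unanimous ensemble reports its value with zero spread", {
  ens <- constant_ensemble(rep(0.5, 20))
  res <- predict_one(ens, carbon_counts())
  expect_equal(res$status, "ok")
  expect_equal(res$mean, 0.5)
  expect_equal(res$sd, 0)
  expect_equal(res$n_valid, 20L)
})

test_that("the guarded protocol applies its steps in the stated order", {
  # 11 of 20 outside the sanity range: strict majority fails the prediction
  ens <- constant_ensemble(c(rep(3.0, 11), rep(0.5, 9)))
  res <- predict_one(ens, carbon_counts())
  expect_equal(res$status, "failure")
  expect_equal(res$failure_reason, "too_many_out_of_range")

  # exactly 10 of 20 is not "more than" half: prediction proceeds
  ens10 <- constant_ensemble(c(rep(3.0, 10), rep(0.5, 10)))
  res10 <- predict_one(ens10, carbon_counts())
  expect_equal(res10$status, "ok")
  expect_equal(res10$mean, 0.5)
  expect_equal(res10$n_valid, 10L)

  # surviving values are clipped to [-2, 2] before aggregation
  ens_clip <- constant_ensemble(rep(2.4, 20))
  expect_equal(predict_one(ens_clip, carbon_counts())$mean, 2.0)

  # a value outside the sanity range is discarded, never clipped: if 2.6
  # were clipped to 2 the mean would rise above 1.0
  ens_ord <- constant_ensemble(c(rep(2.6, 5), rep(1.0, 15)))
  res_ord <- predict_one(ens_ord, carbon_counts())
  expect_equal(res_ord$status, "ok")
  expect_equal(res_ord$mean, 1.0)
  expect_equal(res_ord$n_valid, 15L)

  # ensemble spread above 30% of the 4-log-unit acceptable range fails
  ens_sd <- constant_ensemble(c(rep(2.4, 10), rep(-0.6, 10)))
  res_sd <- predict_one(ens_sd, carbon_counts())
  expect_equal(res_sd$sd, 1.3)  # population sd of clipped values 2.0 / -0.6
  expect_equal(res_sd$status, "failure")
  expect_equal(res_sd$failure_reason, "sd_too_large")

  # spread exactly at the threshold passes (strict inequality)
  ens_sd2 <- constant_ensemble(c(rep(1.2, 10), rep(-1.2, 10)))
  expect_equal(predict_one(ens_sd2, carbon_counts())$status, "ok")
})

test_that("a successful prediction retains at least half the ensemble", {
  cases <- list(rep(0.5, 20), c(rep(3.0, 10), rep(0.5, 10)),
                c(rep(-4, 3), rep(0.2, 17)))
  for (v in cases) {
    res <- predict_one(constant_ensemble(v), carbon_counts())
    if (res$status == "ok") {
      expect_gte(res$n_valid, 0.5 * length(v))
    }
  }
})

test_that("members that cannot featurize a compound count as failures", {
  ens <- constant_ensemble(rep(0.5, 4))
  # compound with no fragment known to any member
  res <- predict_one(ens, stats::setNames(3L, "L1|A|Xx"))
  expect_equal(res$status, "failure")
  expect_equal(res$n_valid, 0L)
})

test_that("a linear ensemble yields analytic fragment contributions", {
  keys <- c("L1|A|C", "L1|A|N", "L1|A|O")
  w <- c(0.3, -0.8, 0.2)
  ens <- linear_ensemble(keys, w)
  cmpds <- tibble::tibble(id = c("ethylamine", "ethanol"),
                          smiles = c("CCN", "CCO"))
  rep_ <- fragment_contributions(ens, cmpds)
  per <- rep_$per_compound
  # contribution of fragment i on compound c is w_i * count_i(c)
  expect_equal(per$contribution[per$id == "ethylamine" & per$key == "L1|A|N"],
               -0.8 * 1, tolerance = 1e-8)
  expect_equal(per$contribution[per$id == "ethylamine" & per$key == "L1|A|C"],
               0.3 * 2, tolerance = 1e-8)
  # fragment absent from a compound contributes exactly zero there
  expect_equal(per$contribution[per$id == "ethylamine" & per$key == "L1|A|O"],
               0)
  # report is ranked most negative to most positive
  expect_equal(rep_$per_fragment$key[1], "L1|A|N")
  expect_false(is.unsorted(rep_$per_fragment$mean_contribution))
})

test_that("aggregated contributions pool credit across refinement levels", {
  # two members carrying the same substructure at different levels: the
  # aggregate at level 1 must combine both credits
  m1 <- linear_ensemble("L1|A|N", w = -0.4)
  m2 <- linear_ensemble("L2|A|N.ss.al", w = -0.2)
  ens <- m1
  ens$members <- c(m1$members, m2$members)
  cmpds <- tibble::tibble(id = "diethylamine", smiles = "CCNCC")
  rep_ <- fragment_contributions(ens, cmpds)
  agg <- aggregate_contributions(rep_, "L1|A|N")
  # each member's contribution is halved by the 2-member average
  expect_equal(agg$total_contribution, (-0.4 * 1 - 0.2 * 1) / 2,
               tolerance = 1e-8)
})

test_that("contributions are invariant under catalog column permutation", {
  keys <- c("L1|A|C", "L1|A|N", "L1|A|O")
  ens <- linear_ensemble(keys, c(0.3, -0.8, 0.2))
  ens_perm <- linear_ensemble(keys[c(3, 1, 2)], c(0.2, 0.3, -0.8))
  cmpds <- tibble::tibble(id = "x", smiles = "NCCO")
  r1 <- fragment_contributions(ens, cmpds)$per_fragment
  r2 <- fragment_contributions(ens_perm, cmpds)$per_fragment
  expect_equal(r1, r2)
})

test_that("batch prediction computes validation statistics against experiment", {
  keys <- c("L1|A|C", "L1|A|N")
  w <- c(0.25, -0.6)
  ens <- linear_ensemble(keys, w)
  cmpds <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    smiles = c("CC", "CCN", "CCCC", "NCCN")
  )
  parsed <- parse_compounds(cmpds)$compounds
  # set the endpoint exactly to the model output: R = 1, RMSE = 0
  exact <- vapply(parsed$graph, function(g) {
    fc <- count_fragments(g, 6, 1)
    cnt <- stats::setNames(fc$count, fc$key)
    sum(w * ifelse(is.na(cnt[keys]), 0, cnt[keys]))
  }, numeric(1))
  parsed$logbb <- exact
  bp <- predict_batch(ens, parsed)
  expect_equal(bp$summary$r, 1, tolerance = 1e-8)
  expect_equal(bp$summary$rmse, 0, tolerance = 1e-8)
  expect_equal(bp$summary$n_abs_err_gt_1, 0)

  # constant predictions: correlation undefined, flagged not crashed
  ens_const <- constant_ensemble(rep(0.4, 6))
  bp2 <- predict_batch(ens_const, parsed)
  expect_true(bp2$summary$r_degenerate)
  expect_true(is.na(bp2$summary$r))
})

test_that("a trained model predicts its own training compounds sensibly", {
  tm <- tiny_model()
  bp <- predict_batch(tm$model$ensemble, tm$data$compounds)
  expect_gte(bp$summary$n_ok, 0.9 * nrow(tm$data$compounds))
  expect_gte(bp$summary$r, 0.8)
  expect_lte(bp$summary$rmse, 0.35)
})
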