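test_that("curation applies the endpoint, organic and duplicate rules with full accounting", {
  df <- tibble::tibble(
    id = c("low", "dup1", "dup2", "salt", "broken", "conf1", "conf2", "ok"),
    smiles = c("CCO", "c1ccccc1O", "Oc1ccccc1", "[Na+].[Cl-]", ")(",
               "CCN", "NCC", "CCCC"),
    logbb = c(-3.0, 0.10, 0.12, 0.2, 0.1, 0.5, 1.2, 0.3)
  )
  cur <- curate(df)
  # every input row lands exactly once in kept or rejects
  expect_setequal(c(cur$kept$id, cur$rejects$id), df$id)
  expect_equal(nrow(cur$kept) + nrow(cur$rejects), nrow(df))

  expect_equal(cur$rejects$reason[cur$rejects$id == "low"], "out_of_range")
  expect_equal(cur$rejects$reason[cur$rejects$id == "salt"], "inorganic")
  expect_equal(cur$rejects$reason[cur$rejects$id == "broken"], "parse_failure")

  # agreeing duplicates merge to their mean and are flagged
  merged <- cur$kept[cur$kept$id == "dup1", ]
  expect_equal(merged$logbb, 0.11)
  expect_true(merged$merged)
  expect_equal(cur$rejects$reason[cur$rejects$id == "dup2"],
               "merged_duplicate")

  # conflicting duplicates (spread > 0.3) are all rejected
  expect_equal(cur$rejects$reason[cur$rejects$id %in% c("conf1", "conf2")],
               rep("conflicting_duplicate", 2))

  # idempotence on the kept table
  cur2 <- curate(cur$kept[, c("id", "smiles", "logbb")])
  expect_equal(nrow(cur2$kept), nrow(cur$kept))
  expect_equal(sort(cur2$kept$logbb), sort(cur$kept$logbb))
  expect_equal(nrow(cur2$rejects), 0)
})

test_that("structure overlap is decided by canonical keys across formats", {
  a <- tibble::tibble(id = c("a1", "a2"), smiles = c("CCO", "CCN"))
  expect_equal(find_overlap(a, a)$overlapping, c("a1", "a2"))
  b <- tibble::tibble(id = "b1", smiles = "c1ccccc1")
  ov <- find_overlap(a, b)
  expect_length(ov$overlapping, 0)
  expect_setequal(ov$non_overlapping, c("a1", "a2"))

  # same molecule as SMILES in one set and SDF-derived graph in the other
  g <- parse_structure("OCC", id = "sdf_ethanol")
  b2 <- tibble::tibble(id = "sdf_ethanol",
                       graph = list(parse_structure(write_sdf_block(g),
                                                    "sdf")))
  expect_equal(find_overlap(a, b2)$overlapping, "a1")
})

test_that("external validation reports transfer statistics and outliers", {
  tm <- tiny_model()
  # held-out synthetic compounds from the same generator
  ext <- generate_dataset(synthetic_spec(n_compounds = 60, noise_sd = 0.15,
                                         max_atoms = 6, levels = 1:2,
                                         seed = 77))$compounds
  rep_ <- validate_external(tm$model$ensemble, ext,
                            train = tm$data$compounds)
  expect_gte(rep_$summary$n, 40)
  expect_gte(rep_$summary$r, 0.6)
  expect_lte(rep_$summary$rmse, 0.6)
  expect_true(all(c("pct_abs_err_gt_1", "sd_error_cor") %in%
                    names(rep_$summary)))
  expect_true(is.data.frame(rep_$by_overlap))
  # outlier table only contains absolute errors above 1 log unit
  if (nrow(rep_$outliers)) expect_true(all(rep_$outliers$abs_error > 1))

  # unrealistic external values are excluded, nothing else is curated
  ext2 <- dplyr::bind_rows(ext[1:5, ],
                           tibble::tibble(id = "far", smiles = "CCO",
                                          logbb = -7, graph = list(
                                            parse_structure("CCO"))))
  rep2 <- validate_external(tm$model$ensemble, ext2[, c("id", "smiles",
                                                        "logbb")])
  expect_equal(rep2$n_excluded, 1L)

  # empty external set: empty report, no crash
  empty <- validate_external(tm$model$ensemble,
                             tibble::tibble(id = character(0),
                                            smiles = character(0),
                                            logbb = numeric(0)))
  expect_equal(nrow(empty$predictions), 0)
})

test_that("the end-to-end trainer produces a self-contained model with manifest", {
  tm <- tiny_model()
  model <- tm$model
  expect_s3_class(model$cv, "cv_result")
  expect_gte(model$cv$Q2, 0.7)
  expect_equal(model$ensemble$featurize$max_atoms, 6)
  expect_equal(model$manifest$n_compounds, 120)
  expect_equal(model$manifest$dcv$seed, 5)
  expect_match(model$manifest$dataset_fingerprint, "^n120-h")

  path <- tempfile(fileext = ".json")
  write_manifest(model, path)
  m <- jsonlite::fromJSON(path)
  expect_equal(m$n_descriptors, ncol(model$dm$counts))

  # prediction on a new molecule built only from grammar moieties
  res <- predict_one(model$ensemble, "CCOC")
  expect_true(res$status %in% c("ok", "failure"))
  expect_equal(res$id, "CCOC")
})

test_that("glance on a model consolidates cross-validation and ensemble facts", {
  tm <- tiny_model()
  g <- glance(tm$model)
  expect_true(all(c("Q2", "RMSEcv", "n_members", "median_stopped_epoch") %in%
                    names(g)))
  expect_equal(g$n_members, 20L)
})
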