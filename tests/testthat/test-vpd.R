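test_that("dataset assembly follows the half/pool/split protocol", {
  pools <- synthetic_twin_pools(30)
  ds <- assemble_ml_dataset(pools$healthy, pools$diseased, seed = 3)
  # Step 2: exactly 50/50 class balance in the pool
  labs <- vapply(ds$pool, `[[`, "", "label")
  expect_equal(sum(labs == "healthy"), 15)
  expect_equal(sum(labs == "diseased"), 15)
  # Step 3: 2/3 train, 1/3 test (floor on test)
  expect_equal(length(ds$test), 10)
  expect_equal(length(ds$train), 20)
  # no subject appears with both labels anywhere
  ids <- vapply(ds$pool, `[[`, NA_integer_, "id")
  expect_equal(anyDuplicated(ids), 0)
  # partitions are disjoint by subject id
  expect_length(intersect(vapply(ds$train, `[[`, NA_integer_, "id"),
                          vapply(ds$test, `[[`, NA_integer_, "id")), 0)
})

test_that("the early-stopping split is 50/25/25", {
  pools <- synthetic_twin_pools(40)
  ds <- assemble_ml_dataset(pools$healthy, pools$diseased, seed = 3,
                            early_stopping = TRUE)
  expect_equal(length(ds$train), 20)
  expect_equal(length(ds$validation), 10)
  expect_equal(length(ds$test), 10)
  expect_length(unique(c(vapply(ds$train, `[[`, NA_integer_, "id"),
                         vapply(ds$validation, `[[`, NA_integer_, "id"),
                         vapply(ds$test, `[[`, NA_integer_, "id"))), 40)
})

test_that("five resplits share one pool but differ in their test sets", {
  pools <- synthetic_twin_pools(40)
  folds <- fivefold_resplits(pools$healthy, pools$diseased, seed = 9)
  expect_length(folds, 5)
  key <- function(pats) sort(paste(vapply(pats, `[[`, NA_integer_, "id"),
                                   vapply(pats, `[[`, "", "label")))
  pool_keys <- lapply(folds, function(f) key(f$pool))
  for (k in 2:5) expect_identical(pool_keys[[k]], pool_keys[[1]])
  test_keys <- lapply(folds, function(f) key(f$test))
  for (a in 1:4) for (b in (a + 1):5)
    expect_false(identical(test_keys[[a]], test_keys[[b]]))
  # deterministic under the master seed
  folds2 <- fivefold_resplits(pools$healthy, pools$diseased, seed = 9)
  expect_identical(lapply(folds, function(f) key(f$test)),
                   lapply(folds2, function(f) key(f$test)))
})

test_that("unpaired pools are rejected", {
  pools <- synthetic_twin_pools(10)
  expect_error(assemble_ml_dataset(pools$healthy[1:9], pools$diseased[1:8]))
  bad <- pools$diseased
  bad[[1]]$id <- 99L
  expect_error(assemble_ml_dataset(pools$healthy, bad), "twin")
})

test_that("sampled severities are uniform on the configured band", {
  set.seed(123)
  s <- replicate(1500, sample_disease("AAA")$severity)
  ks <- suppressWarnings(stats::ks.test(s, "punif", 7.13, 25.93))
  expect_gt(ks$p.value, 0.01)
  set.seed(124)
  s <- replicate(1500, sample_disease("CAS")$severity)
  ks <- suppressWarnings(stats::ks.test(s, "punif", 0.5, 0.95))
  expect_gt(ks$p.value, 0.01)
})

test_that("healthy subject sampling is reproducible and filtered", {
  net <- default_network()
  set.seed(1); a <- sample_healthy_subject(net, id = 1)
  set.seed(1); b <- sample_healthy_subject(net, id = 1)
  expect_identical(a$parameters, b$parameters)
  expect_equal(a$waveforms$samples, b$waveforms$samples)
  # the accepted subject satisfies the plausibility box
  p <- a$waveforms$samples[, "P2_R"]
  expect_true(max(p) >= 90 && max(p) <= 180)
  expect_true(min(p) >= 50 && min(p) <= 100)
  # degenerate variability reproduces the reference network's output
  vc0 <- variability_config(t_range = c(0.9, 0.9), scale_width = 0,
                            asymmetry_width = 0)
  set.seed(2); s1 <- sample_healthy_subject(net, 1, vc = vc0)
  set.seed(3); s2 <- sample_healthy_subject(net, 2, vc = vc0)
  expect_equal(s1$waveforms$samples, s2$waveforms$samples)
})

test_that("diseased twins share the subject, differ in waveforms", {
  net <- default_network()
  vpd <- generate_vpd(net, 3, form = "AAA", seed = 77)
  expect_length(vpd$healthy, 3)
  expect_length(vpd$diseased, 3)
  for (i in 1:3) {
    h <- vpd$healthy[[i]]; d <- vpd$diseased[[i]]
    expect_identical(h$parameters, d$parameters)
    expect_identical(h$id, d$id)
    expect_equal(d$disease$chain, "AA")
    expect_gt(max(abs(h$waveforms$samples - d$waveforms$samples)), 0.1)
  }
  # healthy twins are bit-identical to a pure healthy generation run
  vpd_h <- generate_vpd(net, 3, form = "none", seed = 77)
  expect_equal(vpd$healthy[[1]]$waveforms$samples,
               vpd_h$healthy[[1]]$waveforms$samples)
  # CAS lesions land on a carotid chain with a definite side
  vpd_c <- generate_vpd(net, 2, form = "CAS", seed = 78)
  for (d in vpd_c$diseased) {
    expect_equal(d$disease$chain, "CA")
    expect_true(d$disease$side %in% c("right", "left"))
    expect_equal(d$disease$kind, "stenosis")
  }
})
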