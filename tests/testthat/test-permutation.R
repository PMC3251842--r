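test_that("random signature draws are seeded, uniform, and bounded by the pool", {
  pool <- paste0("p", 1:13)
  draws <- draw_random_signatures(pool, 13, 5, seed = 1)
  for (d in draws) expect_setequal(d, pool)          # forced outcome
  expect_identical(draw_random_signatures(pool, 3, 50, seed = 9),
                   draw_random_signatures(pool, 3, 50, seed = 9))
  expect_error(draw_random_signatures(pool, 14, 1),
               class = "mirsig_validation_error")

  big_pool <- paste0("p", 1:378)
  sigs <- draw_random_signatures(big_pool, 13, 4000, seed = 2)
  freq <- table(factor(unlist(sigs), levels = big_pool)) / 4000
  expected <- 13 / 378
  se <- sqrt(expected * (1 - expected) / 4000)
  expect_lt(max(abs(freq - expected)), 5 * se)
  expect_equal(mean(freq), expected, tolerance = 1e-12)
})

test_that("the empirical adjusted p-value is exact count arithmetic", {
  # the worked example: outperforming 9510 of 10,000 random signatures
  res <- permutation_result(10000, 9510)
  expect_identical(res$empirical_p, 0.049)
  expect_identical(res$empirical_p, (10000 - res$n_outperformed) / res$n_random)
  # worst case: candidate below every random signature
  expect_identical(permutation_result(10000, 0)$empirical_p, 1)
  # continuity-corrected variant
  expect_identical(permutation_result(10000, 9510, continuity = TRUE)$empirical_p,
                   491 / 10001)
  expect_error(permutation_result(100, 101), class = "mirsig_validation_error")
})

test_that("the vectorized permutation test equals per-signature DLDA refits", {
  pr <- processed_experiment(small_config(seed = 71))
  train <- pr$dct[, pr$train]; labels <- pr$labels[pr$train]
  ev <- pr$dct[, pr$validation]; evl <- pr$labels[pr$validation]
  res <- permutation_test(pr$exp$signature, train, labels,
                          evaluation = ev, eval_labels = evl,
                          n = 40, seed = 72)
  sigs <- draw_random_signatures(assay_pool <- setdiff(rownames(train),
                                                       attr(train, "control_probes")),
                                 pr$exp$signature$k, 40, seed = 72)
  naive <- vapply(sigs, function(ids) {
    fit <- dlda(train, labels, probes = ids)
    mean(predict(fit, ev)$call == evl)
  }, numeric(1))
  expect_equal(res$random_metrics, naive, tolerance = 1e-12)
  fit_c <- dlda(train, labels, probes = pr$exp$signature$probe_ids)
  expect_equal(res$candidate_metric,
               mean(predict(fit_c, ev)$call == evl), tolerance = 1e-12)
  expect_identical(res$n_outperformed, sum(naive < res$candidate_metric))
  expect_identical(res$empirical_p, (40 - res$n_outperformed) / 40)
})

test_that("the leave-one-out metric variant equals per-signature LOOCV refits", {
  pr <- processed_experiment(small_config(seed = 73))
  train <- pr$dct[, pr$train]; labels <- pr$labels[pr$train]
  res <- permutation_test(pr$exp$signature, train, labels,
                          n = 25, seed = 74, metric = "loocv_accuracy")
  pool <- setdiff(rownames(train), attr(train, "control_probes"))
  sigs <- draw_random_signatures(pool, pr$exp$signature$k, 25, seed = 74)
  naive <- vapply(sigs, function(ids)
    loocv(train, labels, probes = ids)$accuracy, numeric(1))
  expect_equal(res$random_metrics, naive, tolerance = 1e-12)
  expect_equal(res$candidate_metric,
               loocv(train, labels, probes = pr$exp$signature$probe_ids)$accuracy,
               tolerance = 1e-12)
})

test_that("results are reproducible and internally consistent", {
  pr <- processed_experiment(small_config(seed = 75))
  args <- list(pr$exp$signature, pr$dct[, pr$train], pr$labels[pr$train],
               evaluation = pr$dct[, pr$validation],
               eval_labels = pr$labels[pr$validation], n = 200, seed = 76)
  r1 <- do.call(permutation_test, args)
  r2 <- do.call(permutation_test, args)
  expect_identical(r1$random_metrics, r2$random_metrics)
  expect_identical(r1$empirical_p, r2$empirical_p)
  expect_identical(r1$empirical_p,
                   permutation_result(r1$n_random, r1$n_outperformed)$empirical_p)
  expect_identical(r1$n_outperformed,
                   sum(r1$random_metrics < r1$candidate_metric))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_permutation_distribution(r1, path)
  tab <- read.delim(path)
  expect_identical(tab$metric, r1$random_metrics)
})

test_that("planted signal lowers the empirical p well below its no-signal level", {
  # Note: p is not monotone across strong effects — once the candidate
  # saturates its metric, random signatures overlapping the planted set tie
  # it more often as the effect grows, and ties count against the
  # candidate.  The robust property is signal vs no signal.
  med_p <- vapply(c(0, 1.5, 3), function(eff) {
    ps <- vapply(1:20, function(s) {
      pr <- processed_experiment(small_config(seed = 900 + s, effect_cycles = eff))
      permutation_test(pr$exp$signature, pr$dct[, pr$train], pr$labels[pr$train],
                       evaluation = pr$dct[, pr$validation],
                       eval_labels = pr$labels[pr$validation],
                       n = 300, seed = 950 + s)$empirical_p
    }, numeric(1))
    stats::median(ps)
  }, numeric(1))
  expect_lt(med_p[2], med_p[1] / 2)
  expect_lt(med_p[3], med_p[1] / 2)
})

test_that("candidate probes outside the pool and empty evaluation sets are rejected", {
  pr <- processed_experiment(small_config(seed = 77))
  expect_error(permutation_test(c("nonexistent-probe"), pr$dct[, pr$train],
                                pr$labels[pr$train],
                                evaluation = pr$dct[, pr$validation],
                                eval_labels = pr$labels[pr$validation], n = 5),
               "nonexistent", class = "mirsig_validation_error")
  expect_error(permutation_test(pr$exp$signature, pr$dct[, pr$train],
                                pr$labels[pr$train], n = 5),
               class = "mirsig_validation_error")
})
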