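fit_toy <- function(values, labels) {
  dlda(values, stats::setNames(labels, colnames(values)))
}

test_that("fitting reproduces hand-computed means and pooled variances", {
  vals <- matrix(c(0, 2, 4, 6), 1, dimnames = list("p1", paste0("s", 1:4)))
  fit <- fit_toy(vals, c("resistant", "resistant", "sensitive", "sensitive"))
  expect_identical(fit$means["resistant", "p1"], 1)
  expect_identical(fit$means["sensitive", "p1"], 5)
  expect_identical(unname(fit$variances), 2)          # (1+1+1+1)/2
  expect_false(any(fit$floored))

  # zero within-class spread triggers the variance floor
  vals2 <- matrix(c(0, 0, 2, 2), 1, dimnames = list("p1", paste0("s", 1:4)))
  fit2 <- fit_toy(vals2, c("resistant", "resistant", "sensitive", "sensitive"))
  expect_identical(unname(fit2$variances), fit2$variance_floor)
  expect_true(all(fit2$floored))
})

test_that("fit preconditions are enforced", {
  vals <- matrix(rnorm(8), 2, dimnames = list(c("p1", "p2"), paste0("s", 1:4)))
  labels <- stats::setNames(c("resistant", "resistant", "sensitive", "sensitive"),
                            colnames(vals))
  expect_error(dlda(vals, labels, probes = c("p1", "p9")), "p9",
               class = "mirsig_validation_error")
  expect_error(dlda(vals[, 1:3], labels[1:3]), "2 training samples",
               class = "mirsig_validation_error")
})

test_that("scores follow the diagonal-Gaussian arithmetic and the identity-line rule", {
  vals <- matrix(c(0, 0, 0, 0, 2, 2, 2, 2), 2,
                 dimnames = list(c("p1", "p2"), paste0("s", 1:4)))
  fit <- fit_toy(vals, c("resistant", "resistant", "sensitive", "sensitive"))
  fit$variances[] <- c(1, 4)    # pin variances for the hand example
  pr <- predict(fit, c(p1 = 1, p2 = 2))
  expect_equal(pr$score_resistant, -0.5 * (1 / 1 + 4 / 4))   # -1.0
  expect_equal(pr$score_sensitive, -0.5 * (1 / 1 + 0 / 4))   # -0.5
  expect_identical(pr$call, "sensitive")

  # x at the sensitive mean scores 0 and is called sensitive
  pr_mu <- predict(fit, c(p1 = 2, p2 = 2))
  expect_identical(pr_mu$score_sensitive, 0)
  expect_gte(pr_mu$score_sensitive, pr_mu$score_resistant)
  expect_identical(pr_mu$call, "sensitive")

  # exact midpoint: zero margin resolves to resistant (conservative tie rule)
  pr_mid <- predict(fit, c(p1 = 1, p2 = 1))
  expect_identical(pr_mid$margin, 0)
  expect_identical(pr_mid$call, "resistant")

  expect_error(predict(fit, c(1, 2, 3)), class = "mirsig_validation_error")
})

test_that("calls agree exactly with a brute-force log-density oracle", {
  # moderate-size version of the full acceptance sweep
  set.seed(501)
  for (rep in 1:200) {
    p <- sample(2:5, 1)
    n_r <- sample(2:6, 1); n_s <- sample(2:6, 1)
    probes <- paste0("p", seq_len(p))
    vals <- matrix(rnorm(p * (n_r + n_s), sd = runif(1, 0.5, 2)), p,
                   dimnames = list(probes, paste0("s", seq_len(n_r + n_s))))
    vals[, seq_len(n_s) + n_r] <- vals[, seq_len(n_s) + n_r] + runif(p, -2, 2)
    labels <- stats::setNames(rep(c("resistant", "sensitive"), c(n_r, n_s)),
                              colnames(vals))
    fit <- dlda(vals, labels)
    x <- rnorm(p, mean = rowMeans(vals), sd = 1)
    names(x) <- probes
    expect_identical(predict(fit, x)$call,
                     oracle_dlda_call(x, fit$means["resistant", ],
                                      fit$means["sensitive", ], fit$variances))
  }
})

test_that("batch prediction is a vectorized score_sample and handles the empty set", {
  pr <- processed_experiment(small_config(seed = 31))
  sig <- pr$exp$signature$probe_ids
  fit <- dlda(pr$dct[, pr$train], pr$labels[pr$train], probes = sig)
  batch <- predict(fit, pr$dct[, pr$validation])
  singles <- do.call(rbind, lapply(pr$validation, function(s)
    score_sample(fit, pr$dct[sig, s, drop = TRUE])))
  expect_equal(batch$margin, singles$margin, tolerance = 1e-12)
  expect_identical(batch$call, singles$call)
  empty <- predict(fit, pr$dct[, character(0)])
  expect_identical(nrow(empty), 0L)
  # resubstitution on separable planted data is perfect
  resub <- predict(fit, pr$dct[, pr$train], actual = pr$labels[pr$train])
  expect_true(all(resub$call == resub$actual))
})

test_that("calls are invariant to per-probe shifts and global scaling", {
  pr <- processed_experiment(small_config(seed = 32))
  sig <- pr$exp$signature$probe_ids
  train <- pr$dct[, pr$train]; test <- pr$dct[, pr$validation]
  fit <- dlda(train, pr$labels[pr$train], probes = sig)
  base_calls <- predict(fit, test)$call

  shift <- stats::setNames(runif(nrow(train), -5, 5), rownames(train))
  fit_sh <- dlda(unclass(train) + shift, pr$labels[pr$train], probes = sig)
  expect_identical(predict(fit_sh, unclass(test) + shift)$call, base_calls)

  # rescaling data rescales means and variances together: calls unchanged
  fit_sc <- dlda(unclass(train) * 7, pr$labels[pr$train], probes = sig)
  sc <- predict(fit_sc, unclass(test) * 7)
  expect_identical(sc$call, base_calls)
})

test_that("margin increases strictly along the path from the resistant to the sensitive mean", {
  vals <- matrix(c(0, 1, 0, 1, 3, 2, 3, 2), 2,
                 dimnames = list(c("p1", "p2"), paste0("s", 1:4)))
  fit <- fit_toy(vals, c("resistant", "resistant", "sensitive", "sensitive"))
  mu_r <- fit$means["resistant", ]; mu_s <- fit$means["sensitive", ]
  ts <- seq(0, 1, by = 0.1)
  margins <- vapply(ts, function(t)
    predict(fit, mu_r + t * (mu_s - mu_r))$margin, numeric(1))
  expect_true(all(diff(margins) > 0))
})

test_that("leave-one-out validation scores held-out samples and reports accuracy", {
  pr <- processed_experiment(small_config(seed = 33))
  cv <- loocv(pr$dct[, pr$train], pr$labels[pr$train],
              probes = pr$exp$signature$probe_ids)
  expect_identical(nrow(cv$results), length(pr$train))
  expect_identical(cv$accuracy, mean(cv$results$correct))
  expect_identical(cv$accuracy, 1)           # separable planted design
  expect_error(loocv(pr$dct[, pr$train[c(1, 2, 5, 6, 7)]],
                     pr$labels[pr$train[c(1, 2, 5, 6, 7)]]),
               "3 samples", class = "mirsig_validation_error")
})

test_that("label permutation drives leave-one-out accuracy to chance", {
  pr <- processed_experiment(small_config(seed = 34))
  train <- pr$dct[, pr$train]
  sig <- pr$exp$signature$probe_ids
  set.seed(502)
  accs <- replicate(60, {
    perm <- stats::setNames(sample(pr$labels[pr$train]), pr$train)
    loocv(train, perm, probes = sig)$accuracy
  })
  expect_gt(mean(accs), 0.25)
  expect_lt(mean(accs), 0.75)
})

test_that("the discordant resistant line is the single leave-one-out failure", {
  pr <- processed_experiment(sim_config(discordant_sample = TRUE, seed = 35))
  cv <- loocv(pr$dct[, pr$train], pr$labels[pr$train],
              probes = pr$exp$signature$probe_ids)
  expect_identical(cv$results$sample_id[!cv$results$correct], "RES-4")
  expect_identical(cv$accuracy, 7 / 8)
})

test_that("JSON serialization round-trips a model's predictions", {
  pr <- processed_experiment(small_config(seed = 36))
  fit <- dlda(pr$dct[, pr$train], pr$labels[pr$train],
              probes = pr$exp$signature$probe_ids)
  path <- withr::local_tempfile(fileext = ".json")
  write_dlda(fit, path)
  back <- read_dlda(path)
  expect_identical(back$probes, fit$probes)
  expect_equal(back$means, fit$means, tolerance = 1e-15)
  expect_equal(predict(back, pr$dct[, pr$validation]),
               predict(fit, pr$dct[, pr$validation]), tolerance = 1e-12)
})
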