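test_that("configuration invariants are enforced with informative errors", {
  expect_error(sim_config(signature_size = 5, n_up_in_sensitive = 4,
                          n_down_in_sensitive = 2),
               "n_up_in_sensitive", class = "mirsig_config_error")
  expect_error(sim_config(n_probes = 10, signature_size = 11,
                          n_up_in_sensitive = 10, n_down_in_sensitive = 1),
               "signature_size", class = "mirsig_config_error")
  expect_error(sim_config(noise_sd = 0), "noise_sd", class = "mirsig_config_error")
  expect_error(sim_config(baseline_ct_range = c(10, 32)),
               "baseline_ct_range", class = "mirsig_config_error")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("same config and seed reproduce the experiment bit-exactly", {
  cfg <- small_config(seed = 42)
  e1 <- simulate_card_experiment(cfg)
  e2 <- simulate_card_experiment(cfg)
  expect_identical(e1$ct$values, e2$ct$values)
  expect_identical(e1$ct$detected, e2$ct$detected)
  expect_identical(e1$annotation, e2$annotation)
  expect_identical(e1$signature$probe_ids, e2$signature$probe_ids)
  e3 <- simulate_card_experiment(cfg, seed = 43)
  expect_false(identical(e1$ct$values, e3$ct$values))
})

test_that("planted class shift is recovered from the generated matrix", {
  # up-regulated probes should sit ~effect_cycles lower in sensitive samples
  cfg <- sim_config(seed = 7)
  pr <- processed_experiment(cfg)
  up <- pr$exp$signature$metrics$up_in_sensitive
  sens <- intersect(pr$train, names(pr$labels)[pr$labels == "sensitive"])
  res <- intersect(pr$train, names(pr$labels)[pr$labels == "resistant"])
  diffs <- rowMeans(pr$dct[up, sens]) - rowMeans(pr$dct[up, res])
  se <- cfg$noise_sd * sqrt(1 / length(sens) + 1 / length(res))
  expect_true(all(abs(diffs + cfg$effect_cycles) < 3 * se * sqrt(1 + 1/3) + 1e-9))
  # control probes carry no class effect
  ctrl_raw <- impute_undetected(pr$exp$ct)$values[pr$exp$ct$control_probes, , drop = FALSE]
  cdiff <- rowMeans(ctrl_raw[, sens, drop = FALSE]) - rowMeans(ctrl_raw[, res, drop = FALSE])
  expect_true(all(abs(cdiff) < 5 * sqrt(cfg$noise_sd^2 + cfg$sample_offset_sd^2) *
                    sqrt(1/4 + 1/4)))
})

test_that("a zero-effect design produces a calibrated t-test null", {
  rates <- vapply(1:25, function(s) {
    pr <- processed_experiment(sim_config(effect_cycles = 0, seed = s))
    st <- probe_t_test(pr$dct[, pr$train], pr$labels[pr$train])
    mean(st$p_value < 0.05)
  }, numeric(1))
  n_tests <- 25 * 381
  ci <- 0.05 + c(-1, 1) * qnorm(0.9975) * sqrt(0.05 * 0.95 / n_tests)
  expect_gt(mean(rates), ci[1])
  expect_lt(mean(rates), ci[2])
})

test_that("undetected fraction is monotone in baseline Ct", {
  # probes simulated near the ceiling drop out at least as often as low ones
  cfg <- sim_config(n_probes = 60, n_controls = 2, signature_size = 2,
                    n_up_in_sensitive = 1, n_down_in_sensitive = 1,
                    effect_cycles = 0.5, baseline_ct_range = c(30, 38),
                    n_validation = c(cell_line = 30, primary = 0, metastatic = 0),
                    seed = 99)
  e <- simulate_card_experiment(cfg)
  imputed <- impute_undetected(e$ct)
  base_rank <- rank(rowMeans(imputed$values))
  undet_frac <- rowMeans(!e$ct$detected)
  lo <- undet_frac[base_rank <= 20]
  hi <- undet_frac[base_rank > 40]
  expect_gte(mean(hi), mean(lo))
  expect_gt(length(e$ct$detected), 1000)   # enough simulated wells to judge
  expect_gt(sum(!e$ct$detected), 0)
})

test_that("swapping class designations mirrors the planted effect distribution", {
  # label symmetry: up-shift seen from the sensitive side of an (u, d) design
  # matches the negated down-shift of the transposed (d, u) design
  stat_for <- function(up, down, seeds) {
    vapply(seeds, function(s) {
      cfg <- sim_config(n_probes = 50, n_controls = 3, signature_size = 3,
                        n_up_in_sensitive = up, n_down_in_sensitive = down,
                        n_validation = c(cell_line = 0, primary = 0, metastatic = 0),
                        seed = s)
      pr <- processed_experiment(cfg)
      ids <- if (up >= down) pr$exp$signature$metrics$up_in_sensitive
             else pr$exp$signature$metrics$down_in_sensitive
      sens <- names(pr$labels)[pr$labels == "sensitive"]
      res <- names(pr$labels)[pr$labels == "resistant"]
      mean(rowMeans(pr$dct[ids, sens, drop = FALSE]) -
             rowMeans(pr$dct[ids, res, drop = FALSE]))
    }, numeric(1))
  }
  a <- stat_for(2, 1, 1:100)        # up-probes, expect ~ -effect
  b <- stat_for(1, 2, 101:200)      # down-probes, expect ~ +effect
  expect_equal(mean(a), -mean(b), tolerance = 0.1)
  expect_equal(sd(a), sd(b), tolerance = 0.25)
})

test_that("the discordant-sample option swaps one resistant line onto the sensitive profile", {
  cfg <- sim_config(discordant_sample = TRUE, seed = 5)
  pr <- processed_experiment(cfg)
  up <- pr$exp$signature$metrics$up_in_sensitive
  disc <- "RES-4"
  sens <- setdiff(names(pr$labels)[pr$labels == "sensitive"], pr$validation)
  other_res <- setdiff(pr$train, c(sens, disc))
  d_disc <- mean(pr$dct[up, disc]) - mean(rowMeans(pr$dct[up, other_res]))
  expect_lt(d_disc, -cfg$effect_cycles / 2)   # expresses the sensitive profile
  expect_identical(pr$labels[[disc]], "resistant")
})

test_that("fixture bundles round-trip losslessly including Undetermined wells", {
  cfg <- small_config(seed = 8, baseline_ct_range = c(30, 38))
  e <- simulate_card_experiment(cfg)
  expect_gt(sum(!e$ct$detected), 0)   # at least one Undetermined well
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(e, dir)
  expect_true(all(file.exists(paths)))
  back <- load_ct_table(paths[["ct_table"]])
  expect_identical(back$values, e$ct$values)
  expect_identical(back$detected, e$ct$detected)
  expect_identical(back$control_probes, e$ct$control_probes)
  ann <- read_annotation(paths[["annotation"]])
  expect_identical(ann$sample_id, e$annotation$sample_id)
  expect_identical(ann$label, e$annotation$label)
  sig <- read_signature_file(paths[["signature"]])
  expect_identical(sig$probe_ids, e$signature$probe_ids)
  expect_identical(sig$k, as.integer(cfg$signature_size))
})

test_that("a toy matrix with undetected wells serializes as the Undetermined token", {
  vals <- matrix(c(20, 25, NA, 30, NA, 35), 3,
                 dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  ct <- toy_ct(vals)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ct_table(ct, path)
  expect_identical(sum(grepl("Undetermined", readLines(path))), 2L)
  back <- load_ct_table(path, control_probes = character())
  expect_identical(back$values, ct$values)
  expect_identical(back$detected, ct$detected)
})
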