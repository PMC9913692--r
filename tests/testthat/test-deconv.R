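# Noiseless mixtures built exactly from the signature: the ground truth for
# coefficient recovery in both fitting modes.
truth_w <- c(alpha = 0.6, beta = 0.3, gamma = 0.1, delta = 0, acinar = 0,
             ductal = 0)
mix_w <- as.vector(signature_fixture %*% truth_w)
names(mix_w) <- rownames(signature_fixture)

test_that("NNLS recovers noiseless proportions exactly", {
  fit <- fit_coefficients(mix_w, signature_fixture,
                          deconv_config(mode = "nnls"))
  prop <- fit$coefficients / sum(fit$coefficients)
  expect_lt(max(abs(prop - truth_w)), 1e-6)
  expect_true(is.na(fit$chosen_nu))
})

test_that("nu-SVR agrees with the truth and the NNLS oracle", {
  fit <- fit_coefficients(mix_w, signature_fixture, deconv_config(mode = "svr"))
  prop <- fit$coefficients / sum(fit$coefficients)
  expect_lt(mean(abs(prop - truth_w)), 0.02)
  fit_nnls <- fit_coefficients(mix_w, signature_fixture,
                               deconv_config(mode = "nnls"))
  prop_nnls <- fit_nnls$coefficients / sum(fit_nnls$coefficients)
  expect_lt(max(abs(prop - prop_nnls)), 0.02)
  expect_true(fit$chosen_nu %in% deconv_config()$nu_grid)
})

test_that("a pure signature column deconvolves to a one-hot proportion", {
  y <- signature_fixture[, "beta"]
  for (mode in c("svr", "nnls")) {
    fit <- fit_coefficients(y, signature_fixture, deconv_config(mode = mode))
    prop <- fit$coefficients / sum(fit$coefficients)
    expect_gt(prop[["beta"]], 0.98)
    expect_lt(max(prop[names(prop) != "beta"]), 0.02)
  }
})

test_that("insufficient gene overlap and constant mixtures are handled", {
  short <- mix_w[1:5]
  expect_error(fit_coefficients(short, signature_fixture), "signature genes")
  flat <- rep(1, nrow(signature_fixture))
  names(flat) <- rownames(signature_fixture)
  fit <- fit_coefficients(flat, signature_fixture)
  expect_true(fit$degenerate)
  expect_true(all(fit$coefficients == 0))
})

test_that("reconstruction metrics satisfy their algebraic identities", {
  fit <- fit_coefficients(mix_w, signature_fixture, deconv_config(mode = "nnls"))
  met <- reconstruction_metrics(mix_w, signature_fixture, fit$coefficients)
  expect_lt(met$rmse, 1e-8)
  expect_gt(met$pearson_r, 1 - 1e-10)
  # all-zero coefficients: rmse equals the RMS of the standardized mixture
  zero <- fit$coefficients * 0
  expect_warning(
    met0 <- reconstruction_metrics(mix_w, signature_fixture, zero),
    "constant reconstruction")
  expect_identical(met0$pearson_r, 0)
  genes <- rownames(signature_fixture)
  ys <- (mix_w[genes] - mean(mix_w[genes])) / sd(mix_w[genes])
  expect_equal(met0$rmse, sqrt(mean(ys^2)), tolerance = 1e-12)
  # negated coefficients flip the reconstruction: r = -1
  met_neg <- reconstruction_metrics(mix_w, signature_fixture,
                                    -fit$coefficients)
  expect_equal(met_neg$pearson_r, -1, tolerance = 1e-10)
})

test_that("empirical p-value hits its closed-form extremes and is seeded", {
  cfg <- deconv_config(mode = "nnls", n_permutations = 100L, seed = 9L)
  full <- mix_w  # full profile = the signature genes here
  # a real mixture reconstructs better than every permutation
  p_lo <- empirical_p_value(full, signature_fixture, observed_r = 0.9999,
                            config = cfg)
  expect_equal(p_lo, 1 / 101)
  # observed r below every permutation
  p_hi <- empirical_p_value(full, signature_fixture, observed_r = -1,
                            config = cfg)
  expect_equal(p_hi, 1, tolerance = 1 / 101)
  # determinism under a fixed seed
  p_a <- empirical_p_value(full, signature_fixture, 0.5, cfg, seed = 33L)
  p_b <- empirical_p_value(full, signature_fixture, 0.5, cfg, seed = 33L)
  expect_identical(p_a, p_b)
  expect_error(empirical_p_value(mix_w[1:10], signature_fixture, 0.5, cfg),
               "shorter than the signature")
})

test_that("cohort deconvolution isolates degenerate samples and is order-stable", {
  mix <- simulate_bulk_mixtures(signature_fixture, n_samples = 6,
                                proportions = "dirichlet", seed = 21,
                                noise = "none")
  bulk <- mix$matrix
  bulk[, 3] <- 0  # an all-zero sample
  cfg <- deconv_config(mode = "nnls", n_permutations = 10L, seed = 2L)
  res <- suppressMessages(deconvolve_cohort(bulk, signature_fixture,
                                            mixed_model, cfg))
  expect_identical(res$status[3], "degenerate")
  expect_true(all(res$status[-3] == "ok"))
  ok <- res$status == "ok"
  est <- as.matrix(res[ok, paste0("prop_", colnames(signature_fixture))])
  truth <- as.matrix(mix$truth[ok, colnames(signature_fixture)])
  expect_lt(max(abs(est - truth)), 1e-6)
  # permuting sample order permutes rows, nothing else
  perm <- c(4, 1, 6, 2, 3, 5)
  res_perm <- suppressMessages(deconvolve_cohort(bulk[, perm],
                                                 signature_fixture,
                                                 mixed_model, cfg))
  reordered <- res[match(res_perm$sample_id, res$sample_id), ]
  rownames(reordered) <- NULL
  expect_equal(res_perm, reordered)
})

test_that("relative proportions are a simplex and aggregation is exact", {
  mix <- simulate_bulk_mixtures(profiles_fixture, n_samples = 8,
                                noise = "nb", nb_dispersion = 0.3, seed = 5)
  cfg <- deconv_config(mode = "nnls", n_permutations = 0L)
  res <- suppressMessages(deconvolve_cohort(mix$matrix, signature_fixture,
                                            mixed_model, cfg))
  props <- as.matrix(res[, paste0("prop_", colnames(signature_fixture))])
  expect_true(all(props >= 0))
  expect_true(all(abs(rowSums(props) - 1) < 1e-9))
  expect_identical(res$model_exocrine_like, res$prop_acinar + res$prop_ductal)
  mprops <- as.matrix(res[, paste0("model_", mixed_model$model_types)])
  expect_true(all(abs(rowSums(mprops) - 1) < 1e-9))
})

test_that("feature extraction yields the documented vectors", {
  mix <- simulate_bulk_mixtures(signature_fixture, n_samples = 3, seed = 8,
                                noise = "none")
  cfg <- deconv_config(mode = "nnls", n_permutations = 5L)
  res <- suppressMessages(deconvolve_cohort(mix$matrix, signature_fixture,
                                            mixed_model, cfg))
  feat <- extract_features(res, mixed_model)
  expect_identical(dim(feat), c(3L, 8L))
  expect_identical(colnames(feat),
                   c("alpha", "beta", "gamma", "delta", "exocrine_like",
                     "p_value", "rmse", "pearson_r"))
  endo <- cell_type_model("endocrine_only")
  res_e <- suppressMessages(deconvolve_cohort(mix$matrix, signature_fixture,
                                              endo, cfg))
  feat_e <- extract_features(res_e, endo)
  expect_identical(ncol(feat_e), 7L)
  # identical reruns give identical features
  res2 <- suppressMessages(deconvolve_cohort(mix$matrix, signature_fixture,
                                             mixed_model, cfg))
  expect_identical(extract_features(res2, mixed_model), feat)
})
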