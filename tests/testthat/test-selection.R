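fast_cfg <- function(n, seed = 1, steps = 5e4) {
  sas_config(ensemble_size = n, n_steps = steps, seed = seed)
}

test_that("a single perfectly matching conformer is found at N = 1", {
  prob <- small_problem()
  ds <- prob$ds
  ds$rdc_hz <- prob$mat$values[17, ]  # conformer 17 is the exact truth
  res <- sas_select(prob$mat, ds, fast_cfg(1, seed = 2))
  expect_equal(res$member_indices, 17)
  expect_lt(res$rmsd_hz, 1e-9)
})

test_that("noise-free selection reaches the generating ensemble's cost", {
  prob <- small_problem()
  res <- sas_select(prob$mat, prob$ds, fast_cfg(4, seed = 5, steps = 1e5))
  true_calc <- ensemble_average(prob$mat, prob$members)
  true_rmsd <- rdc_rmsd(true_calc, prob$ds,
                        fit_scale_factors(true_calc, prob$ds))
  expect_lte(res$rmsd_hz, true_rmsd + 1e-6)
  expect_lt(res$rmsd_hz, 1e-6)
  # recovered ensemble average equals the generator's
  sel_calc <- ensemble_average(prob$mat, res$member_indices)
  expect_equal(unname(res$scales[prob$ds$construct]) * sel_calc,
               prob$ds$rdc_hz, tolerance = 1e-6)
})

test_that("sas results satisfy their structural invariants", {
  prob <- small_problem()
  cfg <- fast_cfg(4, seed = 9)
  res <- sas_select(prob$mat, prob$ds, cfg)
  # distinct members within the library
  expect_length(unique(res$member_indices), 4)
  expect_true(all(res$member_indices %in% seq_len(60)))
  # best-cost trace is monotone non-increasing
  expect_true(all(diff(res$trace) <= 1e-12))
  # chi2 / rmsd relation and agreement with a from-scratch evaluation
  expect_equal(res$rmsd_hz, sqrt(res$chi2 / nrow(prob$ds)),
               tolerance = 1e-12)
  calc <- ensemble_average(prob$mat, res$member_indices)
  expect_equal(res$rmsd_hz,
               rdc_rmsd(calc, prob$ds, fit_scale_factors(calc, prob$ds)),
               tolerance = 1e-9)
  # bit-reproducible given the seed
  res2 <- sas_select(prob$mat, prob$ds, cfg)
  expect_identical(res$member_indices, res2$member_indices)
  expect_identical(res$chi2, res2$chi2)
  # different seeds converge to the same cost on this easy problem
  res3 <- sas_select(prob$mat, prob$ds, fast_cfg(4, seed = 10, steps = 3e5))
  res5 <- sas_select(prob$mat, prob$ds, fast_cfg(4, seed = 11, steps = 3e5))
  expect_lt(abs(res3$rmsd_hz - res5$rmsd_hz), 1e-6)
  expect_error(sas_select(prob$mat, prob$ds, fast_cfg(100)), "exceeds")
})

test_that("selection beats random ensembles almost always", {
  prob <- small_problem()
  # make it non-trivial: noisy data
  truth <- simulated_truth(prob$members, prob$tensors, noise_sd = 2)
  ds <- simulate_rdc_dataset(prob$lib, truth, 40, seed = 44)
  mat <- precompute_matrix(prob$lib, ds, mode = "fixed-tensor",
                           tensors = prob$tensors)
  res <- sas_select(mat, ds, fast_cfg(4, seed = 3))
  set.seed(99)
  wins <- vapply(1:40, function(k) {
    idx <- sample.int(60, 4)
    calc <- ensemble_average(mat, idx)
    res$rmsd_hz <= rdc_rmsd(calc, ds, fit_scale_factors(calc, ds))
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})

test_that("fixed-scale mode is supported", {
  prob <- small_problem()
  cfg <- fast_cfg(4, seed = 2)
  cfg$refit_scales <- FALSE
  cfg$fixed_scales <- stats::setNames(rep(1, 3), unique(prob$ds$construct))
  res <- sas_select(prob$mat, prob$ds, cfg)
  expect_equal(unname(res$scales), rep(1, 3))
  calc <- ensemble_average(prob$mat, res$member_indices)
  expect_equal(res$rmsd_hz, rdc_rmsd(calc, prob$ds, res$scales),
               tolerance = 1e-9)
})

test_that("size scans report per-size statistics and the plateau", {
  prob <- small_problem()
  # noisy data: larger ensembles keep improving the (noise-limited) fit
  truth <- simulated_truth(prob$members, prob$tensors, noise_sd = 2)
  ds <- simulate_rdc_dataset(prob$lib, truth, 40, seed = 53)
  mat <- precompute_matrix(prob$lib, ds, mode = "fixed-tensor",
                           tensors = prob$tensors)
  sc <- size_scan(mat, ds, sizes = c(1, 2, 4, 6), replicates = 2,
                  seed = 3, config = sas_config(n_steps = 4e4))
  expect_equal(sc$n, c(1, 2, 4, 6))
  # mean RMSD non-increasing in N within replicate noise
  expect_true(all(diff(sc$mean_rmsd) <= 0.3))
  expect_false(is.na(attr(sc, "plateau_index")))
  one <- size_scan(mat, ds, sizes = 2, replicates = 2, seed = 3,
                   config = sas_config(n_steps = 2e4))
  expect_equal(nrow(one), 1)
})

test_that("the plateau rule flags the first sub-tolerance improvement", {
  expect_equal(plateau_index(c(9, 5, 3.1, 3.0, 3.0), tol = 0.2), 3)
  expect_equal(plateau_index(c(9, 5, 3.1), tol = 0.2), NA_integer_)
  expect_equal(plateau_index(c(4, 3.95, 3.9), tol = 0.2), 1)
})

test_that("pooled runs keep per-run provenance and sane fits", {
  prob <- small_problem()
  cfg <- fast_cfg(4, seed = 6, steps = 3e4)
  pool <- pool_runs(prob$mat, prob$ds, cfg, total_size = 20)
  expect_length(pool$members, 20)
  expect_equal(pool$n_runs, 5)
  expect_equal(as.vector(table(pool$run)), rep(4, 5))
  expect_error(pool_runs(prob$mat, prob$ds, cfg, total_size = 21),
               "divisible")
  # a single-run pool is exactly one selection
  one <- pool_runs(prob$mat, prob$ds, cfg, total_size = 4)
  expect_identical(sort(one$members),
                   sas_select(prob$mat, prob$ds, cfg)$member_indices)
  # every run beats the library-mean baseline
  base_calc <- colMeans(prob$mat$values)
  base <- rdc_rmsd(base_calc, prob$ds,
                   fit_scale_factors(base_calc, prob$ds))
  expect_true(all(pool$run_rmsd_hz <= base))
})

test_that("random-holdout cross-validation holds out the stated share", {
  prob <- small_problem()
  cv <- crossval_random(prob$mat, prob$ds, fast_cfg(4, steps = 2e4),
                        fraction = 0.10, repeats = 3, seed = 2)
  expect_equal(cv$repeats, 3)
  expect_equal(nrow(cv$per_fold), 3)
  # 120 records, 10% -> 12 held out; rmsd finite and reproducible
  cv2 <- crossval_random(prob$mat, prob$ds, fast_cfg(4, steps = 2e4),
                         fraction = 0.10, repeats = 3, seed = 2)
  expect_identical(cv$heldout_rmsd_hz, cv2$heldout_rmsd_hz)
  expect_error(crossval_random(prob$mat, prob$ds, fast_cfg(4),
                               fraction = 0), "fraction")
  expect_error(crossval_random(prob$mat, prob$ds, fast_cfg(4),
                               fraction = 1e-4), "empty")
})

test_that("media cross-validation leaves out whole constructs", {
  prob <- small_problem()
  cv <- crossval_media(prob$mat, prob$ds, fast_cfg(4, steps = 2e4), seed = 7)
  expect_equal(cv$repeats, 3)
  expect_setequal(cv$per_fold$construct, unique(prob$ds$construct))
  one <- rdcens:::subset_matrix(prob$mat,
                                which(prob$ds$construct == "construct1"))
  expect_error(crossval_media(one, config = fast_cfg(4)), ">= 2 constructs")
  # exchangeability: duplicated construct, noise-free, held-out ~ training
  ds1 <- rdcens:::subset_dataset(prob$ds, prob$ds$construct == "construct1")
  ds_dup <- rbind(ds1, transform(ds1, construct = "construct1b"))
  class(ds_dup) <- class(prob$ds)
  tensors2 <- prob$tensors[c(1, 1)]
  names(tensors2) <- c("construct1", "construct1b")
  mat2 <- precompute_matrix(prob$lib, ds_dup, mode = "fixed-tensor",
                            tensors = tensors2)
  cvd <- crossval_media(mat2, ds_dup, fast_cfg(4, steps = 5e4), seed = 4)
  expect_lt(max(abs(cvd$per_fold$heldout_rmsd_hz -
                      cvd$per_fold$train_rmsd_hz)), 0.2)
})
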