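# Sample-and-select (SAS): simulated-annealing Monte Carlo selection of an
# N-conformer ensemble that minimizes the scaled squared misfit between
# ensemble-averaged predicted and measured RDCs, plus ensemble-size
# scanning, multi-run pooling and the two cross-validation schemes.

#' SAS configuration
#'
#' Defaults follow the published protocol: effective starting temperature
#' 100, cooling by a factor 0.9 at every proposal step, 5e5 total steps.
#' With per-step cooling the chain is effectively greedy after a few hundred
#' steps; `cool_every` allows a slower block-cooling cadence.
#'
#' @param ensemble_size number of (distinct) members N.
#' @param t_initial starting effective temperature.
#' @param cool_factor per-cooling-event temperature multiplier in (0, 1).
#' @param n_steps total Monte Carlo proposal steps.
#' @param temperature_floor lower bound on the temperature.
#' @param seed integer RNG seed.
#' @param refit_scales refit per-construct scale factors at every cost
#'   evaluation (default) or keep them fixed.
#' @param fixed_scales named per-construct scales used when
#'   `refit_scales = FALSE` (default: least-squares fit to the library-mean
#'   prediction).
#' @param cool_every apply the cooling factor every this many steps. The
#'   default (`NULL`) spreads the full temperature schedule (t_initial down
#'   to the floor) over the whole run, so the chain anneals rather than
#'   quenches; set to 1 for a literal per-proposal-step cooling, which is
#'   effectively a greedy quench after a few hundred steps.
#' @param restarts independent annealing restarts per selection (each runs
#'   `n_steps` steps from a fresh random ensemble with a derived seed); the
#'   best ensemble across restarts is returned. Restarts escape the local
#'   minima of the single-swap move set on rugged landscapes.
#' @param pair_move_prob fraction of proposals that exchange two members at
#'   once; pair moves cross cost barriers that no single swap can.
#' @param checkpoint_every trace the best cost every this many steps.
#' @return list of class `sas_config`.
#' @export
sas_config <- function(ensemble_size = 20, t_initial = 100,
                       cool_factor = 0.9, n_steps = 5e5,
                       temperature_floor = 1e-12, seed = 1L,
                       refit_scales = TRUE, fixed_scales = NULL,
                       cool_every = NULL, checkpoint_every = 1000L,
                       restarts = 1L, pair_move_prob = 0.25) {
  stopifnot(restarts >= 1, pair_move_prob >= 0, pair_move_prob <= 1)
  if (is.null(cool_every)) {
    n_coolings <- log(temperature_floor / t_initial) / log(cool_factor)
    cool_every <- max(1, floor(n_steps / n_coolings))
  }
  stopifnot(ensemble_size >= 1, n_steps >= 1,
            cool_factor > 0, cool_factor < 1,
            t_initial > 0, temperature_floor > 0, cool_every >= 1)
  structure(list(ensemble_size = as.integer(ensemble_size),
                 t_initial = t_initial, cool_factor = cool_factor,
                 n_steps = as.integer(n_steps),
                 temperature_floor = temperature_floor,
                 seed = as.integer(seed), refit_scales = refit_scales,
                 fixed_scales = fixed_scales,
                 cool_every = as.integer(cool_every),
                 checkpoint_every = as.integer(checkpoint_every),
                 restarts = as.integer(restarts),
                 pair_move_prob = pair_move_prob),
            class = "sas_config")
}

# Stated counter-based seed derivation for reproducible multi-run schemes.
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) + 77003 * as.numeric(counter)) %% 2147483647)
}

#' Select an ensemble by simulated-annealing Monte Carlo
#'
#' Initializes with N distinct uniform draws from the library; each step
#' proposes replacing one uniformly chosen member by a uniformly chosen
#' non-member and accepts with probability min(1, exp(-dcost/T)). The cost
#' is the mean squared residual between scaled ensemble-averaged predictions
#' and measurements, with per-construct scales refit at every evaluation
#' (configurable). The best-ever ensemble is returned. Fully reproducible
#' per seed.
#'
#' @param matrix an [rdc_matrix()] of per-conformer predictions.
#' @param dataset the [rdc_dataset()] (must match the matrix).
#' @param config a [sas_config()].
#' @return list of class `sas_result`: `member_indices` (sorted, distinct),
#'   `scales`, `chi2` (sum of squared scaled residuals, Hz^2; the annealing
#'   cost is `chi2`/N_records), `rmsd_hz` (= sqrt(chi2/N_records)),
#'   `trace` (best cost per checkpoint, non-increasing), `seed`.
#' @export
sas_select <- function(matrix, dataset = matrix$dataset,
                       config = sas_config()) {
  stopifnot(inherits(matrix, "rdc_matrix"), inherits(config, "sas_config"))
  if (nrow(dataset) != ncol(matrix$values))
    stop("dataset does not match the prediction matrix")
  nlib <- nrow(matrix$values)
  n <- config$ensemble_size
  if (n > nlib)
    stop("ensemble size ", n, " exceeds library size ", nlib)
  constructs <- unique(dataset$construct)
  cidx <- match(dataset$construct, constructs) - 1L
  pred <- t(matrix$values)  # records x conformers
  fixed <- rep(1, length(constructs))
  if (!config$refit_scales) {
    fixed <- if (!is.null(config$fixed_scales))
      unname(config$fixed_scales[constructs])
    else unname(fit_scale_factors(colMeans(matrix$values), dataset))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  if (n == nlib) {
    # no non-member to swap in; the ensemble is the whole library
    calc <- colMeans(matrix$values)
    scales <- fit_scale_factors(calc, dataset)
    rmsd <- rdc_rmsd(calc, dataset, scales)
    return(structure(list(member_indices = seq_len(nlib),
                          scales = scales, chi2 = rmsd^2 * nrow(dataset),
                          rmsd_hz = rmsd, trace = rmsd^2, seed = config$seed),
                     class = "sas_result"))
  }
  # per-step cooling with a block cadence: fold cool_every into the factor
  cool <- if (config$cool_every == 1) config$cool_factor
  else config$cool_factor^(1 / config$cool_every)
  res <- NULL
  trace <- numeric(0)
  for (r in seq_len(config$restarts)) {
    set.seed(if (r == 1) config$seed else derive_seed(config$seed, 500 + r))
    init <- sample.int(nlib, n)
    this <- .sas_core(pred, dataset$rdc_hz, cidx, length(constructs),
                      as.integer(init), config$n_steps, config$t_initial,
                      cool, config$temperature_floor, config$refit_scales,
                      as.numeric(fixed), config$checkpoint_every,
                      config$pair_move_prob)
    trace <- cummin(c(trace, this$trace))
    if (is.null(res) || this$best_cost < res$best_cost) res <- this
  }
  res$trace <- trace
  members <- sort(res$members)
  calc <- ensemble_average(matrix, members)
  scales <- if (config$refit_scales) fit_scale_factors(calc, dataset)
  else stats::setNames(fixed, constructs)
  rmsd <- rdc_rmsd(calc, dataset, scales)
  structure(list(member_indices = members, scales = scales,
                 chi2 = rmsd^2 * nrow(dataset), rmsd_hz = rmsd,
                 trace = res$trace * nrow(dataset), seed = config$seed),
            class = "sas_result")
}

#' @export
print.sas_result <- function(x, ...) {
  cat(sprintf("<sas_result> N = %d, RDC RMSD %.3f Hz (chi2 %.3f)\n",
              length(x$member_indices), x$rmsd_hz, x$chi2))
  invisible(x)
}

#' Scan ensemble sizes
#'
#' Runs independent SAS selections for each size and replicate (seeds
#' derived from `seed` by a counter scheme) and reports mean and standard
#' deviation of the RDC RMSD per size, flagging the plateau where the
#' improvement of the mean RMSD over the next size drops below `tol`.
#'
#' @param matrix an [rdc_matrix()].
#' @param dataset the [rdc_dataset()].
#' @param sizes ensemble sizes to try.
#' @param replicates SAS runs per size.
#' @param seed master seed.
#' @param config template [sas_config()] (size and seed are overridden).
#' @param tol plateau tolerance on the mean-RMSD improvement (Hz).
#' @return data.frame with `n`, `mean_rmsd`, `sd_rmsd`, `plateau`;
#'   attribute `plateau_index` gives the first plateau position (NA if the
#'   scan never flattens).
#' @export
size_scan <- function(matrix, dataset = matrix$dataset, sizes,
                      replicates = 3, seed = 1L, config = sas_config(),
                      tol = 0.2) {
  stopifnot(length(sizes) >= 1)
  rows <- lapply(seq_along(sizes), function(si) {
    r <- vapply(seq_len(replicates), function(k) {
      cfg <- config
      cfg$ensemble_size <- as.integer(sizes[si])
      cfg$seed <- derive_seed(seed, (si - 1) * replicates + k)
      sas_select(matrix, dataset, cfg)$rmsd_hz
    }, 0)
    data.frame(n = sizes[si], mean_rmsd = mean(r),
               sd_rmsd = if (replicates > 1) stats::sd(r) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$plateau <- c(diff(out$mean_rmsd) > -tol, NA)
  attr(out, "plateau_index") <- plateau_index(out$mean_rmsd, tol)
  out
}

#' Plateau position of an RMSD-vs-size series
#'
#' First position whose improvement over the next size is below `tol`.
#'
#' @param means mean RMSD per size, in scan order.
#' @param tol improvement tolerance (Hz).
#' @return integer index, or NA if the series never flattens.
#' @export
plateau_index <- function(means, tol = 0.2) {
  flat <- which(-diff(means) < tol)
  if (length(flat) == 0) NA_integer_ else flat[1]
}

#' Pool members from repeated SAS runs
#'
#' Runs `total_size / N` independent selections with derived seeds and pools
#' the selected members into one multiset of size `total_size` with per-run
#' provenance (the protocol used to build large ensembles, e.g.
#' 20 x 100 = 2000, for distribution analyses).
#'
#' @param matrix an [rdc_matrix()].
#' @param dataset the [rdc_dataset()].
#' @param config a [sas_config()]; its seed is the master seed.
#' @param total_size pooled size; must be divisible by the ensemble size.
#' @return list of class `sas_pool`: `members` (length `total_size`),
#'   `run` (provenance), `run_rmsd_hz` (per run), `n_runs`.
#' @export
pool_runs <- function(matrix, dataset = matrix$dataset, config, total_size) {
  n <- config$ensemble_size
  if (total_size %% n != 0)
    stop("total_size ", total_size, " is not divisible by N = ", n)
  n_runs <- total_size %/% n
  members <- integer(0)
  run <- integer(0)
  rmsds <- numeric(n_runs)
  for (k in seq_len(n_runs)) {
    cfg <- config
    # counter starts at zero so a single-run pool equals one sas_select
    cfg$seed <- derive_seed(config$seed, k - 1)
    res <- sas_select(matrix, dataset, cfg)
    members <- c(members, res$member_indices)
    run <- c(run, rep(k, n))
    rmsds[k] <- res$rmsd_hz
  }
  structure(list(members = members, run = run, run_rmsd_hz = rmsds,
                 n_runs = n_runs),
            class = "sas_pool")
}

subset_dataset <- function(dataset, idx) {
  out <- dataset[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(dataset)
  out
}

subset_matrix <- function(matrix, record_idx) {
  rdc_matrix(matrix$values[, record_idx, drop = FALSE],
             subset_dataset(matrix$dataset, record_idx),
             matrix$conformer_ids)
}

#' Cross-validation by random record hold-out
#'
#' Per repeat, a fraction of the records is held out uniformly at random,
#' SAS runs on the remainder, and the held-out RMSD is computed with the
#' training-fit scales (the same constructs remain present). The final
#' figure is the mean over repeats. An ensemble that over-fits noise shows a
#' held-out RMSD clearly above its training RMSD.
#'
#' @param matrix an [rdc_matrix()].
#' @param dataset the [rdc_dataset()].
#' @param config a [sas_config()].
#' @param fraction held-out share of records in (0, 1).
#' @param repeats number of random repeats.
#' @param seed master seed for the hold-out draws and run seeds.
#' @return list of class `crossval_result` with `mode`, `heldout_rmsd_hz`
#'   (mean), `per_fold` (data.frame incl. training RMSD), `repeats`.
#' @export
crossval_random <- function(matrix, dataset = matrix$dataset,
                            config = sas_config(), fraction = 0.10,
                            repeats = 10, seed = config$seed) {
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must be in (0, 1)")
  nrec <- nrow(dataset)
  n_out <- floor(fraction * nrec)
  if (n_out < 1) stop("held-out set empty (", nrec, " records, fraction ",
                      fraction, ")")
  folds <- lapply(seq_len(repeats), function(k) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(derive_seed(seed, 1000 + k))
    held <- sort(sample.int(nrec, n_out))
    cfg <- config
    cfg$seed <- derive_seed(seed, k)
    train_idx <- setdiff(seq_len(nrec), held)
    res <- sas_select(subset_matrix(matrix, train_idx),
                      config = cfg)
    calc_all <- ensemble_average(matrix, res$member_indices)
    data.frame(
      fold = k,
      train_rmsd_hz = res$rmsd_hz,
      heldout_rmsd_hz = rdc_rmsd(calc_all, dataset, res$scales,
                                 subset = held))
  })
  per_fold <- do.call(rbind, folds)
  structure(list(mode = "inactive_random",
                 heldout_rmsd_hz = mean(per_fold$heldout_rmsd_hz),
                 per_fold = per_fold, repeats = repeats),
            class = "crossval_result")
}

#' Cross-validation by leaving out whole constructs
#'
#' One fold per construct: SAS runs on the remaining constructs, and the
#' held-out construct is scored after fitting a single free scale factor on
#' its own data (only the relative RDC pattern of an unseen alignment medium
#' is testable, since alignment magnitude is construct-specific). The final
#' figure is the mean over folds.
#'
#' @inheritParams crossval_random
#' @return a `crossval_result` (mode `inactive_media`).
#' @export
crossval_media <- function(matrix, dataset = matrix$dataset,
                           config = sas_config(), seed = config$seed) {
  constructs <- unique(dataset$construct)
  if (length(constructs) < 2)
    stop("media cross-validation needs >= 2 constructs")
  folds <- lapply(seq_along(constructs), function(k) {
    j <- constructs[k]
    held <- which(dataset$construct == j)
    train_idx <- which(dataset$construct != j)
    cfg <- config
    cfg$seed <- derive_seed(seed, k)
    res <- sas_select(subset_matrix(matrix, train_idx), config = cfg)
    calc_all <- ensemble_average(matrix, res$member_indices)
    held_ds <- subset_dataset(dataset, held)
    l <- fit_scale_factors(calc_all[held], held_ds)
    data.frame(
      fold = k, construct = j,
      train_rmsd_hz = res$rmsd_hz,
      heldout_rmsd_hz = rdc_rmsd(calc_all[held], held_ds, l))
  })
  per_fold <- do.call(rbind, folds)
  structure(list(mode = "inactive_media",
                 heldout_rmsd_hz = mean(per_fold$heldout_rmsd_hz),
                 per_fold = per_fold, repeats = length(constructs)),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("<crossval_result> %s: held-out RDC RMSD %.3f Hz (%d folds)\n",
              x$mode, x$heldout_rmsd_hz, x$repeats))
  invisible(x)
}
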