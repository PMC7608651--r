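# Synthetic conformer libraries and RDC datasets.
#
# The generator emulates the system the pipeline is built for: two idealized
# A-form helices joined by a short single-strand bulge, with a bimodal
# inter-helical bend distribution (a narrow stacked mode and a broad kinked
# mode), heterogeneous bulge sugar puckers, extra-helical flipping coupled
# to coaxiality, and multi-construct RDC sets with per-construct alignment
# tensors, scale factors and Gaussian noise. Every stage of the pipeline is
# testable against the known generating truth without external data.

#' Junction model for the synthetic generator
#'
#' Defaults describe a three-nucleotide pyrimidine bulge between two 4-bp
#' helices with a bimodal bend distribution (stacked-narrow and
#' kinked-broad modes), even odds of C2'-endo bulge puckers, and flip-out
#' probabilities coupled to the coaxial (linear) state.
#'
#' @param bulge_length number of bulge nucleotides (1-7).
#' @param bulge_seq recycled bulge sequence.
#' @param helix1_seq,helix2_seq strand-1 sequences of the lower and upper
#'   helix (strand 2 is the reverse complement).
#' @param bend_modes data.frame with columns `mean`, `sd`, `weight`
#'   (degrees; weights sum to 1): the mixture the bend magnitude `|beta_h|`
#'   is drawn from.
#' @param twist_sd standard deviation of the inter-helical twist (degrees).
#' @param bend_max truncation of the bend distribution (degrees): junctions
#'   more bent than this fold one helix through the other and are redrawn
#'   (the default removes well under 1\% of the default mixture's mass).
#' @param pucker_prob per-bulge-residue probability of a C2'-endo sugar.
#' @param flip_prob_linear,flip_prob_bent per-residue extra-helical
#'   probability when the sampled bend is linear (< 45 deg) vs not, coupling
#'   flipping to coaxiality.
#' @param clash_tol minimum allowed heavy-atom distance (Angstrom).
#' @param max_retries resampling attempts per conformer before erroring.
#' @param seed integer seed.
#' @return list of class `junction_model`.
#' @export
junction_model <- function(bulge_length = 3, bulge_seq = "UCU",
                           helix1_seq = "GCAG", helix2_seq = "GAGC",
                           bend_modes = data.frame(
                             mean = c(15, 75), sd = c(8, 20),
                             weight = c(0.45, 0.55)),
                           twist_sd = 15, bend_max = 115,
                           pucker_prob = 0.5,
                           flip_prob_linear = 0.9, flip_prob_bent = 0.35,
                           clash_tol = 1.5, max_retries = 300, seed = 1L) {
  stopifnot(bulge_length >= 1, bulge_length <= 7,
            abs(sum(bend_modes$weight) - 1) < 1e-9,
            all(bend_modes$weight >= 0),
            pucker_prob >= 0, pucker_prob <= 1,
            flip_prob_linear >= 0, flip_prob_linear <= 1,
            flip_prob_bent >= 0, flip_prob_bent <= 1)
  bseq <- strsplit(toupper(bulge_seq), "")[[1]]
  bseq <- bseq[((seq_len(bulge_length) - 1) %% length(bseq)) + 1]
  structure(list(bulge_length = as.integer(bulge_length), bulge_seq = bseq,
                 helix1_seq = toupper(helix1_seq),
                 helix2_seq = toupper(helix2_seq),
                 bend_modes = bend_modes, twist_sd = twist_sd,
                 bend_max = bend_max,
                 pucker_prob = pucker_prob,
                 flip_prob_linear = flip_prob_linear,
                 flip_prob_bent = flip_prob_bent,
                 clash_tol = clash_tol, max_retries = max_retries,
                 seed = as.integer(seed)),
            class = "junction_model")
}

revcomp <- function(s) {
  paste(rev(unname(wc_partner[strsplit(s, "")[[1]]])), collapse = "")
}

# Residue numbering of the generated construct:
# chain A: lower strand1 (1..h1), bulge (h1+1..h1+L), upper strand1;
# chain B: upper strand2 then lower strand2 (5'->3').
junction_layout <- function(model) {
  h1 <- nchar(model$helix1_seq)
  h2 <- nchar(model$helix2_seq)
  L <- model$bulge_length
  n_a <- h1 + L + h2
  list(
    h1 = h1, h2 = h2, L = L,
    lower1 = 1:h1,
    bulge = (h1 + 1):(h1 + L),
    upper1 = (h1 + L + 1):n_a,
    upper2 = (n_a + 1):(n_a + h2),
    lower2 = (n_a + h2 + 1):(n_a + h2 + h1),
    # closing base pairs of the junction (lower helix top, upper helix bottom)
    closing_lower = c(h1, n_a + h2 + 1),
    closing_upper = c(h1 + L + 1, n_a + h2),
    # cross-junction stacking partners used for the coaxial call
    bridging_pairs = list(c(h1, h1 + L + 1),
                          c(n_a + h2 + 1, n_a + h2),
                          c(h1, n_a + h2),
                          c(n_a + h2 + 1, h1 + L + 1)))
}

# Place one bulge nucleotide template with its C1' at `c1_t`, glycosidic
# bond along `u`, base plane normal along `axis`.
place_bulge_nt <- function(base, pucker, c1_t, u, axis) {
  tmpl <- nucleotide_template(base, pucker)
  an <- attr(tmpl, "anchors")
  g_t <- -unit(u)
  n_part <- axis - sum(axis * g_t) * g_t
  n_t <- if (vnorm(n_part) < 1e-6) unit(cross3(g_t, c(1, 0, 0))) else
    unit(n_part)
  d_t <- as.vector(rot_axis(n_t, an$theta) %*% g_t)
  s <- if (det(cbind(d_t, g_t, n_t)) *
           det(cbind(an$d_hat, an$g_hat, an$n_hat)) >= 0) 1 else -1
  if (s < 0) d_t <- as.vector(rot_axis(n_t, -an$theta) %*% g_t)
  src <- rbind(an$c1, an$n, an$n + an$d_hat, an$n + an$n_hat)
  n_pos <- c1_t + 1.48 * unit(u)
  ns <- unit(cross3(d_t, g_t))
  dst <- rbind(c1_t, n_pos, n_pos + d_t, n_pos + ns)
  fit <- kabsch(src, dst)
  apply_rt(tmpl, fit$R, fit$t)
}

#' Generate a synthetic two-helix bulge conformer library
#'
#' Per conformer, the bend magnitude is drawn from the configured mode
#' mixture, the twist from a normal distribution, bulge sugar puckers and
#' extra-helical flips from their per-residue probabilities (flips coupled
#' to the linear state), the upper helix is rotated about the junction
#' accordingly, and bulge nucleotides are placed intra- or extra-helically.
#' Conformers failing the clash tolerance are resampled up to the configured
#' retry cap. Deterministic for a given model seed.
#'
#' @param model a [junction_model()].
#' @param size number of conformers.
#' @return a [conformer_library()] with attributes `truth` (per-conformer
#'   data.frame of sampled bend/twist/flips/puckers) and `layout`.
#' @export
generate_library <- function(model, size) {
  stopifnot(inherits(model, "junction_model"), size >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(model$seed)
  lay <- junction_layout(model)
  params <- aform_parameters()
  lower_spec <- helix_spec(model$helix1_seq, revcomp(model$helix1_seq),
                           lay$lower1, lay$lower2)
  upper_spec <- helix_spec(model$helix2_seq, revcomp(model$helix2_seq),
                           lay$upper1, lay$upper2)
  lower <- build_aform_helix(lower_spec)
  upper0 <- build_aform_helix(upper_spec)
  rise <- params$rise
  twist <- params$twist_deg
  h1 <- lay$h1
  # the hinge sits on the strand-2 backbone, the strand that runs
  # uninterrupted across the junction: bending opens the two helices like a
  # book instead of folding one body through the other
  pivot <- atom_xyz(lower, lay$closing_lower[2], "C1'") +
    c(0, 0, rise / 2)
  axis_mid <- c(0, 0, (h1 - 0.5) * rise)  # junction point on the helix axis
  # coaxial continuation transform for the upper helix
  k_rot <- rot_z(h1 * twist)
  k_tr <- c(0, 0, h1 * rise)
  # fixed atom table of the construct; only coordinates vary per conformer
  bulge_names <- lapply(seq_len(lay$L), function(b)
    rownames(nucleotide_template(model$bulge_seq[b])))
  lower1_atoms <- lower$atoms[lower$atoms$resno %in% lay$lower1, ]
  lower2_atoms <- lower$atoms[lower$atoms$resno %in% lay$lower2, ]
  bulge_atoms <- do.call(rbind, lapply(seq_len(lay$L), function(b)
    data.frame(resno = lay$bulge[b],
               resname = nt_resnames[[model$bulge_seq[b]]], chain = "A",
               atom = bulge_names[[b]],
               elem = substr(bulge_names[[b]], 1, 1),
               x = 0, y = 0, z = 0, stringsAsFactors = FALSE)))
  atoms0 <- rbind(lower1_atoms, bulge_atoms, upper0$atoms, lower2_atoms)
  rownames(atoms0) <- NULL
  i_bulge <- lapply(lay$bulge, function(r) which(atoms0$resno == r))
  i_upper <- which(atoms0$resno %in% c(lay$upper1, lay$upper2))
  xyz0 <- as.matrix(atoms0[, c("x", "y", "z")])
  mask <- clash_mask(atoms0)
  # the strand-1 backbone jumps across the junction when the helices stack
  # coaxially, so the closing residues of the two helices legitimately come
  # within bonding distance of each other
  rs <- atoms0$resno[atoms0$elem != "H"]
  a <- rs == lay$closing_lower[1]
  b <- rs == lay$closing_upper[1]
  mask <- mask | outer(a, b, "&") | outer(b, a, "&")
  conformers <- vector("list", size)
  truth <- vector("list", size)
  for (i in seq_len(size)) {
    # the bend is drawn once per conformer and kept across clash retries,
    # so rejection cannot bias the sampled bend distribution
    repeat {
      mode_k <- sample.int(nrow(model$bend_modes), 1,
                           prob = model$bend_modes$weight)
      bend <- abs(stats::rnorm(1, model$bend_modes$mean[mode_k],
                               model$bend_modes$sd[mode_k]))
      if (bend <= model$bend_max) break
    }
    # puckers too are drawn once per conformer: clash retries must not bias
    # the configured pucker probabilities
    puckers <- ifelse(stats::runif(lay$L) < model$pucker_prob,
                      "C2'-endo", "C3'-endo")
    for (attempt in seq_len(model$max_retries)) {
      alpha <- stats::runif(1, -180, 180)
      tw <- stats::rnorm(1, 0, model$twist_sd)
      gamma <- tw - alpha
      r_rel <- euler_to_matrix(alpha, bend, gamma)
      up_xyz <- apply_rt(coords(upper0), k_rot, k_tr)
      up_xyz <- sweep((sweep(up_xyz, 2, pivot) %*% t(r_rel)), 2, pivot, `+`)
      # bent junctions open up slightly: push the upper helix along its own
      # axis to relieve the pinch on the inside of the bend
      gap <- 2.0 * sin(bend / 2 * DEG)
      up_xyz <- sweep(up_xyz, 2, gap * as.vector(r_rel %*% c(0, 0, 1)), `+`)
      p_flip <- if (bend <= 45) model$flip_prob_linear else
        model$flip_prob_bent
      flips <- stats::runif(lay$L) < p_flip
      # anchor path for the bulge: lower-helix top strand-1 C1' to
      # upper-helix bottom strand-1 C1'
      a1 <- atom_xyz(lower, lay$lower1[h1], "C1'")
      up_c1_idx <- which(upper0$atoms$resno == lay$upper1[1] &
                           upper0$atoms$atom == "C1'")
      a2 <- up_xyz[up_c1_idx, ]
      axis_lower <- c(0, 0, 1)
      axis_upper <- as.vector(r_rel %*% c(0, 0, 1))
      chain_dir <- unit(axis_lower + axis_upper)
      # bulge nucleotides detour around the junction on an outward arc,
      # fanned azimuthally so consecutive residues do not collide; flipped-in
      # residues hug the junction, flipped-out ones sit further out with the
      # base extending away from the helices
      radial0 <- a1 - axis_mid
      radial0 <- radial0 - sum(radial0 * chain_dir) * chain_dir
      radial0 <- if (vnorm(radial0) < 1e-6) c(1, 0, 0) else unit(radial0)
      xyz <- xyz0
      xyz[i_upper, ] <- up_xyz
      helix_heavy <- xyz[-unlist(i_bulge), , drop = FALSE]
      helix_heavy <- helix_heavy[atoms0$elem[-unlist(i_bulge)] != "H", ,
                                 drop = FALSE]
      for (b in seq_len(lay$L)) {
        t_frac <- b / (lay$L + 1)
        interp <- (1 - t_frac) * a1 + t_frac * a2
        phi <- (b - (lay$L + 1) / 2) * 45
        radial <- as.vector(rot_axis(chain_dir, phi) %*% radial0)
        r_arc <- if (flips[b]) 13 else 10
        # axial component of the path point, plus the radial detour
        axial <- axis_mid + sum((interp - axis_mid) * chain_dir) * chain_dir
        c1_t <- axial + r_arc * radial
        u <- radial  # base points outward, away from the helices
        # of the two base-plane orientations, keep the one whose backbone
        # tail clears the helices better
        best <- NULL
        for (axs in list(chain_dir, -chain_dir)) {
          nt <- place_bulge_nt(model$bulge_seq[b], puckers[b], c1_t, u, axs)
          hv <- nt[substr(rownames(nt), 1, 1) != "H", , drop = FALSE]
          mind <- min(outer(rowSums(hv^2), rowSums(helix_heavy^2), `+`) -
                        2 * hv %*% t(helix_heavy))
          if (is.null(best) || mind > best$mind)
            best <- list(nt = nt, mind = mind)
        }
        nt <- best$nt
        xyz[i_bulge[[b]], ] <- nt[match(atoms0$atom[i_bulge[[b]]],
                                        rownames(nt)), ]
      }
      atoms <- atoms0
      atoms[, c("x", "y", "z")] <- xyz
      conf <- new_conformer(atoms, model_id = i)
      if (!has_clash(conf, model$clash_tol, mask)) break
      if (attempt == model$max_retries)
        stop("could not generate a clash-free conformer ", i, " in ",
             model$max_retries, " attempts")
    }
    conformers[[i]] <- conf
    truth[[i]] <- c(bend, tw, alpha, as.numeric(flips),
                    as.numeric(puckers == "C2'-endo"))
  }
  tt <- do.call(rbind, truth)
  truth_df <- data.frame(
    bend = tt[, 1], twist = tt[, 2], alpha = tt[, 3],
    matrix(as.logical(tt[, 4:(3 + lay$L), drop = FALSE]), nrow = size,
           dimnames = list(NULL, paste0("flip", seq_len(lay$L)))),
    matrix(as.logical(tt[, (4 + lay$L):(3 + 2 * lay$L), drop = FALSE]),
           nrow = size,
           dimnames = list(NULL, paste0("c2endo", seq_len(lay$L)))))
  lib <- conformer_library(conformers, source = "synthetic junction model")
  attr(lib, "truth") <- truth_df
  attr(lib, "layout") <- lay
  lib
}

# Heavy-atom clash test, ignoring pairs within the same or sequentially
# adjacent residues of one chain. `mask` (TRUE = excluded pair) can be
# precomputed once for a fixed atom layout.
clash_mask <- function(atoms) {
  at <- atoms[atoms$elem != "H", ]
  outer(paste(at$chain, at$resno), paste(at$chain, at$resno), "==") |
    (outer(at$chain, at$chain, "==") &
       abs(outer(at$resno, at$resno, "-")) <= 1)
}

has_clash <- function(conf, tol, mask = NULL) {
  at <- conf$atoms[conf$atoms$elem != "H", ]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (is.null(mask)) mask <- clash_mask(conf$atoms)
  sq <- rowSums(xyz^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(xyz)
  d2[mask] <- Inf
  min(d2) < tol^2
}

#' Simulation ground truth
#'
#' @param true_member_indices generating ensemble (library positions).
#' @param true_tensors named list of per-construct [alignment_tensor()]s.
#' @param true_scales named per-construct scale factors.
#' @param noise_sd Gaussian noise on the couplings (Hz); 2 Hz is the typical
#'   experimental error.
#' @return list of class `simulated_truth`.
#' @export
simulated_truth <- function(true_member_indices, true_tensors,
                            true_scales = NULL, noise_sd = 2.0) {
  if (is.null(true_scales))
    true_scales <- stats::setNames(rep(1, length(true_tensors)),
                                   names(true_tensors))
  stopifnot(length(true_scales) == length(true_tensors))
  structure(list(true_member_indices = true_member_indices,
                 true_tensors = true_tensors, true_scales = true_scales,
                 noise_sd = noise_sd),
            class = "simulated_truth")
}

# Random, moderately rhombic Saupe tensors on the experimental scale.
random_tensors <- function(n_constructs, szz = 1.2e-3) {
  out <- list()
  for (j in seq_len(n_constructs)) {
    r <- random_rotation()
    zz <- szz * (0.7 + 0.15 * j)
    eta <- stats::runif(1, 0, 0.5)
    d <- diag(c(-zz * (1 - eta) / 2, -zz * (1 + eta) / 2, zz))
    out[[paste0("construct", j)]] <- alignment_tensor(r %*% d %*% t(r))
  }
  out
}

# Candidate RDC record schema for a library: sugar C1'-H1' plus one base
# C-H per residue.
candidate_records <- function(library) {
  conf <- library$conformers[[1]]
  res <- unique(conf$atoms[, c("resno", "resname")])
  rows <- lapply(seq_len(nrow(res)), function(i) {
    base_pair <- if (is_purine(res$resname[i])) c("C8", "H8") else
      c("C6", "H6")
    data.frame(resno = res$resno[i],
               atom1 = c("C1'", base_pair[1]),
               atom2 = c("H1'", base_pair[2]))
  })
  do.call(rbind, rows)
}

#' Simulate a multi-construct RDC dataset from a known ensemble
#'
#' Predicted couplings of the true members are averaged per construct under
#' that construct's alignment tensor, multiplied by the true scale, and
#' Gaussian noise of `truth$noise_sd` is added. Seeded and reproducible.
#'
#' @param library a [conformer_library()].
#' @param truth a [simulated_truth()]; its tensors define the constructs.
#' @param records_per_construct NULL for the full per-residue schema
#'   (two couplings per nucleotide), or a count sampled from it.
#' @param seed RNG seed for record sampling and noise.
#' @return an [rdc_dataset()].
#' @export
simulate_rdc_dataset <- function(library, truth,
                                 records_per_construct = NULL, seed = 1L) {
  stopifnot(inherits(truth, "simulated_truth"))
  if (any(truth$true_member_indices < 1 |
            truth$true_member_indices > length(library$conformers)))
    stop("true members outside library")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  cand <- candidate_records(library)
  blocks <- lapply(names(truth$true_tensors), function(j) {
    rec <- cand
    if (!is.null(records_per_construct) &&
          records_per_construct < nrow(cand))
      rec <- cand[sort(sample.int(nrow(cand), records_per_construct)), ]
    rec$construct <- j
    rec$rdc_hz <- 0
    rec$error_hz <- max(truth$noise_sd, 0.1)
    ds <- rdc_dataset(rec)
    calc <- rowMeans(vapply(truth$true_member_indices, function(m)
      predict_rdcs(library$conformers[[m]], truth$true_tensors[[j]], ds),
      numeric(nrow(ds))))
    ds$rdc_hz <- truth$true_scales[[j]] * calc +
      stats::rnorm(nrow(ds), 0, truth$noise_sd)
    ds
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  class(out) <- c("rdc_dataset", "data.frame")
  out
}

#' End-to-end parameter-recovery experiment
#'
#' Generates a library, simulates RDCs from a random true K-member ensemble,
#' runs SAS at N = K, and compares the selected ensemble with the truth: a
#' repeat succeeds when the selected cost does not exceed the (exhaustively
#' evaluated) cost of the true member set.
#'
#' @param model a [junction_model()].
#' @param library_size conformers in the generated pool.
#' @param true_n size of the generating (and selected) ensemble.
#' @param config a [sas_config()] template.
#' @param repeats independent repetitions (fresh library, truth and noise).
#' @param n_constructs alignment media to simulate.
#' @param records_per_construct see [simulate_rdc_dataset()].
#' @param noise_sd coupling noise (Hz).
#' @param seed master seed.
#' @return data.frame with per-repeat `rmsd_hz`, `true_rmsd_hz`, `success`,
#'   `jaccard`; summary attributes `success_rate`, `mean_rmsd`.
#' @export
recovery_experiment <- function(model, library_size = 200, true_n = 4,
                                config = sas_config(ensemble_size = true_n),
                                repeats = 10, n_constructs = 3,
                                records_per_construct = 40,
                                noise_sd = 0, seed = 1L) {
  stopifnot(true_n <= library_size)
  rows <- lapply(seq_len(repeats), function(k) {
    m <- model
    m$seed <- derive_seed(seed, 10 * k)
    lib <- generate_library(m, library_size)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(derive_seed(seed, 10 * k + 1))
    true_members <- sort(sample.int(library_size, true_n))
    tensors <- random_tensors(n_constructs)
    truth <- simulated_truth(true_members, tensors, noise_sd = noise_sd)
    ds <- simulate_rdc_dataset(lib, truth, records_per_construct,
                               seed = derive_seed(seed, 10 * k + 2))
    mat <- precompute_matrix(lib, ds, mode = "fixed-tensor",
                             tensors = tensors)
    cfg <- config
    cfg$ensemble_size <- as.integer(true_n)
    cfg$seed <- derive_seed(seed, 10 * k + 3)
    res <- sas_select(mat, ds, cfg)
    true_calc <- ensemble_average(mat, true_members)
    true_rmsd <- rdc_rmsd(true_calc, ds, fit_scale_factors(true_calc, ds))
    data.frame(
      repeat_id = k,
      rmsd_hz = res$rmsd_hz,
      true_rmsd_hz = true_rmsd,
      success = res$rmsd_hz <= true_rmsd + 1e-6,
      jaccard = length(intersect(res$member_indices, true_members)) /
        length(union(res$member_indices, true_members)))
  })
  out <- do.call(rbind, rows)
  attr(out, "success_rate") <- mean(out$success)
  attr(out, "mean_rmsd") <- mean(out$rmsd_hz)
  out
}
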