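test_that("dihedrals follow the standard convention", {
  a <- c(1, 1, 0); b <- c(0, 1, 0); c <- c(0, 0, 0)
  expect_equal(dihedral(a, b, c, c(1, -1, 0)), 0, tolerance = 1e-9)   # cis
  expect_equal(abs(dihedral(a, b, c, c(-1, -1, 0))), 180,
               tolerance = 1e-9)                                      # trans
  expect_equal(dihedral(a, b, c, c(0, -1, 1)),
               -dihedral(a, b, c, c(0, -1, -1)), tolerance = 1e-9)
})

test_that("torsions recover the configured template geometry", {
  h <- tar_like_helix()
  tors <- compute_torsions(h)
  expect_true(all(tors$P > 0 & tors$P < 36))       # C3'-endo templates
  expect_true(all(abs(tors$nu_max - 38.4) < 1))
  expect_equal(tors$chi, rep(-158, 8), tolerance = 1e-6)
  hs <- build_aform_helix(helix_spec("GCAG", "CUGC", 18:21, 41:44),
                          pucker = "C2'-endo")
  ps <- compute_torsions(hs)$P
  expect_true(all(ps > 90 & ps < 270))
  # torsions invariant under rigid motion
  set.seed(6)
  t2 <- compute_torsions(transform_conformer(h, rand_rot(), c(5, -3, 2)))
  num <- vapply(tors, is.numeric, TRUE)
  expect_equal(as.matrix(t2[, num]), as.matrix(tors[, num]),
               tolerance = 1e-6)
  # incomplete residues give NA, not an error
  broken <- h
  broken$atoms <- broken$atoms[!(broken$atoms$resno == 19 &
                                   broken$atoms$atom == "C2'"), ]
  tb <- compute_torsions(broken)
  expect_true(is.na(tb$P[tb$resno == 19]))
  expect_false(anyNA(tb$P[tb$resno != 19]))
})

test_that("pucker classification uses the configured windows", {
  h <- tar_like_helix()
  tors <- compute_torsions(h)
  expect_equal(classify_pucker(tors, 19)$state, "C3'-endo")
  south <- build_aform_helix(helix_spec("GCAG", "CUGC", 18:21, 41:44),
                             pucker = "C2'-endo")
  expect_equal(classify_pucker(compute_torsions(south), 19)$state,
               "C2'-endo")
  flat <- tors[tors$resno == 19, ]
  flat$nu_max <- 5
  expect_equal(classify_pucker(flat, 19)$state, "ambiguous")
  # delta fallback when the ring is incomplete
  broken <- h
  broken$atoms <- broken$atoms[!(broken$atoms$resno == 19 &
                                   broken$atoms$atom == "O4'"), ]
  call <- classify_pucker(compute_torsions(broken), 19)
  expect_match(call$reason, "fallback")
})

test_that("pucker populations count unambiguous members", {
  sp <- helix_spec("GC", "GC", 1:2, 3:4)
  north <- build_aform_helix(sp)
  south <- build_aform_helix(sp, pucker = "C2'-endo")
  ens <- c(rep(list(north), 17), rep(list(south), 3))
  expect_equal(as.numeric(pucker_population(ens, 1)), 0.15)
  expect_equal(as.numeric(pucker_population(rep(list(north), 5), 1)), 0)
  set.seed(2)
  perm <- sample(ens)
  expect_equal(as.numeric(pucker_population(perm, 1)), 0.15)
})

test_that("chemical shifts map linearly onto pucker populations", {
  expect_equal(shift_to_c2endo(86), 100)
  expect_equal(shift_to_c2endo(94), 0)
  expect_equal(shift_to_c2endo(90), 50)
  # affine between the anchors
  s <- seq(86, 94, by = 0.5)
  expect_equal(shift_to_c2endo(s), 100 * (94 - s) / 8, tolerance = 1e-12)
  expect_equal(shift_to_c2endo(85), 100)   # clamped
  expect_equal(shift_to_c2endo(85, clamp = FALSE), 112.5)
  expect_error(shift_to_c2endo(90, 88, 88), "differ")
})

test_that("euler decomposition and recomposition are exact inverses", {
  set.seed(77)
  for (k in 1:1000) {
    r <- rand_rot()
    eu <- matrix_to_euler(r)
    expect_lt(norm(euler_to_matrix(eu$alpha_h, eu$beta_h, eu$gamma_h) - r,
                   "F"), 1e-6)
  }
  # gimbal: pure twist
  eu0 <- matrix_to_euler(rdcens:::rot_z(25))
  expect_equal(eu0$beta_h, 0, tolerance = 1e-9)
  expect_lt(norm(euler_to_matrix(eu0$alpha_h, eu0$beta_h, eu0$gamma_h) -
                   rdcens:::rot_z(25), "F"), 1e-9)
})

test_that("a continuous ideal helix has zero inter-helical bend", {
  h <- build_aform_helix(helix_spec("GCAGGG", "CCCUGC", 1:6, 7:12))
  up <- list(c(4, 9), c(5, 8), c(6, 7))
  lo <- list(c(1, 12), c(2, 11), c(3, 10))
  eu <- interhelical_euler(h, up, lo)
  expect_lt(eu$beta_h, 1e-3)
  expect_lt(max(eu$fit_rmsd), 1e-9)
})

test_that("a constructed junction rotation is recovered", {
  h <- build_aform_helix(helix_spec("GCAGGG", "CCCUGC", 1:6, 7:12))
  up <- list(c(4, 9), c(5, 8), c(6, 7))
  lo <- list(c(1, 12), c(2, 11), c(3, 10))
  sel <- h$atoms$resno %in% c(4:9)
  piv <- c(0, 0, 3.5 * aform_parameters()$rise)
  bent <- h
  bent$atoms[sel, c("x", "y", "z")] <-
    sweep(sweep(coords(h, sel), 2, piv) %*% t(rdcens:::rot_y(60)), 2,
          piv, `+`)
  eu <- interhelical_euler(bent, up, lo)
  expect_equal(eu$bend, 60, tolerance = 0.1)
  # the whole analysis is frame-relative: global motion changes nothing
  set.seed(12)
  moved <- transform_conformer(bent, rand_rot(), c(10, 5, -4))
  eu2 <- interhelical_euler(moved, up, lo)
  expect_equal(c(eu2$alpha_h, eu2$beta_h, eu2$gamma_h),
               c(eu$alpha_h, eu$beta_h, eu$gamma_h), tolerance = 1e-3)
})

test_that("bend categories split at 45 and 70 degrees, ties downward", {
  expect_equal(bend_category(30), "linear")
  expect_equal(bend_category(60), "intermediate")
  expect_equal(bend_category(90), "kinked")
  expect_equal(bend_category(45), "linear")
  expect_equal(bend_category(70), "intermediate")
})

test_that("stacking follows the geometric criterion", {
  h <- tar_like_helix()
  expect_true(detect_stacking(h, 18, 19))   # sequential in the helix
  expect_true(detect_stacking(h, 42, 43))
  expect_false(detect_stacking(h, 18, 44))  # paired: coplanar side-by-side
  expect_false(detect_stacking(h, 18, 21))  # three steps apart
  far <- h
  sel <- far$atoms$resno == 19
  far$atoms[sel, "x"] <- far$atoms[sel, "x"] + 20
  expect_false(detect_stacking(far, 18, 19))
  broken <- h
  broken$atoms <- broken$atoms[!(broken$atoms$resno == 19 &
                                   broken$atoms$atom == "N3"), ]
  expect_true(is.na(detect_stacking(broken, 18, 19)))
})

test_that("coaxial and extra-helical calls work on constructed junctions", {
  coax_model <- junction_model(seed = 21, bend_modes = data.frame(
    mean = 0, sd = 0, weight = 1), twist_sd = 0, flip_prob_linear = 1)
  kink_model <- junction_model(seed = 22, bend_modes = data.frame(
    mean = 90, sd = 0, weight = 1), twist_sd = 0)
  coax <- generate_library(coax_model, 5)
  kink <- generate_library(kink_model, 8)
  lay <- attr(coax, "layout")
  expect_true(all(vapply(coax$conformers, detect_coaxial,
                         NA, lay$bridging_pairs)))
  expect_false(any(vapply(kink$conformers, detect_coaxial,
                          NA, lay$bridging_pairs)))
  expect_error(detect_coaxial(coax$conformers[[1]], list()), "bridging")
  # a base inserted between the closing pairs in helical register is
  # intra-helical; one displaced far out is extra-helical
  h6 <- build_aform_helix(helix_spec("GCAGGG", "CCCUGC", 1:6, 7:12))
  closing <- c(3, 10, 5, 8)  # treat bp 4-9 as the "bulge" residue's slot
  expect_false(detect_extra_helical(h6, 4, closing))
  out <- h6
  sel <- out$atoms$resno == 4
  out$atoms[sel, "x"] <- out$atoms[sel, "x"] + 12
  expect_true(detect_extra_helical(out, 4, closing))
  set.seed(9)
  moved <- transform_conformer(out, rand_rot(), c(-3, 8, 1))
  expect_true(detect_extra_helical(moved, 4, closing))
  expect_false(detect_extra_helical(
    transform_conformer(h6, rand_rot(), c(1, 1, 1)), 4, closing))
})

test_that("cooperativity vanishes exactly for factorized flip tables", {
  set.seed(14)
  for (k in 1:5) {
    p <- sample(1:9, 3, replace = TRUE) / 10
    combos <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                          c = c(TRUE, FALSE))
    counts <- round(1000 * apply(combos, 1, function(z)
      prod(ifelse(z, p, 1 - p))))
    ft <- as.matrix(combos[rep(seq_len(8), counts), ])
    res <- cooperativity(ft)
    expect_equal(res$p_out, p, tolerance = 1e-9)
    expect_equal(res$delta_g, 0, tolerance = 1e-6)
  }
})

test_that("cooperativity reproduces a hand-evaluated table", {
  ft <- rbind(
    matrix(TRUE, 40, 3),                                 # all out: 0.4
    matrix(FALSE, 12, 3),                                # all in
    matrix(rep(c(TRUE, FALSE, FALSE), 4), ncol = 3, byrow = TRUE),
    matrix(rep(c(FALSE, TRUE, FALSE), 3), ncol = 3, byrow = TRUE),
    matrix(rep(c(FALSE, FALSE, TRUE), 3), ncol = 3, byrow = TRUE),
    matrix(rep(c(TRUE, TRUE, FALSE), 38), ncol = 3, byrow = TRUE))
  res <- cooperativity(ft)
  expect_equal(res$p_out, c(0.25, 0.2, 0.2), tolerance = 1e-12)
  expect_equal(res$p_independent, 0.01, tolerance = 1e-12)
  expect_equal(res$p_observed, 0.4, tolerance = 1e-12)
  expect_equal(res$delta_g, -0.0019872041 * 298 * log(40),
               tolerance = 1e-9)
  # the published-style observed fraction: 8 all-out of 20 members
  ft20 <- rbind(matrix(TRUE, 8, 3), matrix(FALSE, 10, 3),
                matrix(rep(c(TRUE, FALSE, FALSE), 2), ncol = 3,
                       byrow = TRUE))
  # only one nucleotide flips alone here, so the independent product is
  # degenerate (flagged); the observed fraction is still well-defined
  expect_warning(res20 <- cooperativity(ft20), "undefined")
  expect_equal(res20$p_observed, 0.4)
  # degenerate table: no reference conformers with the others flipped in
  expect_error(cooperativity(matrix(c(TRUE, TRUE, TRUE, FALSE,
                                      TRUE, FALSE), 2, 3)), "undefined")
})

test_that("superposition rmsd matches independent oracles", {
  prob <- small_problem()
  a <- prob$lib$conformers[[1]]
  expect_equal(superpose_rmsd(a, a), 0, tolerance = 1e-9)
  set.seed(31)
  moved <- transform_conformer(a, rand_rot(), c(4, -7, 2))
  expect_lt(superpose_rmsd(moved, a), 1e-6)
  for (k in 2:4) {
    b <- prob$lib$conformers[[k]]
    ours <- superpose_rmsd(a, b)
    m <- rdcens:::match_selection(a, b)
    expect_equal(ours, horn_rmsd(m$x, m$y), tolerance = 1e-6)
    # established-package cross-check
    fit <- suppressWarnings(
      bio3d::fit.xyz(as.vector(t(m$y)), as.vector(t(m$x))))
    bio3d_rmsd <- sqrt(mean(colSums(
      (matrix(fit, nrow = 3) - t(m$y))^2)))
    expect_equal(ours, bio3d_rmsd, tolerance = 1e-6)
  }
})

test_that("ensemble distance is a symmetric-minimum lower bound", {
  prob <- small_problem()
  a <- prob$lib$conformers[1:3]
  b <- prob$lib$conformers[4:7]
  expect_equal(as.numeric(ensemble_distance(a, a)), 0, tolerance = 1e-9)
  expect_equal(as.numeric(ensemble_distance(a[1], b[1])),
               superpose_rmsd(a[[1]], b[[1]]), tolerance = 1e-12)
  # direct-definition oracle
  pr <- matrix(0, 3, 4)
  for (i in 1:3) for (j in 1:4) pr[i, j] <- superpose_rmsd(a[[i]], b[[j]])
  oracle <- min(sqrt(mean(apply(pr, 1, min)^2)),
                sqrt(mean(apply(pr, 2, min)^2)))
  d <- ensemble_distance(a, b)
  expect_equal(as.numeric(d), oracle, tolerance = 1e-6)
  expect_lte(as.numeric(d), max(pr))
})
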