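test_that("alignment tensors are validated and kept symmetric traceless", {
  m <- diag(c(1e-3, 1e-3, -2e-3))
  tn <- alignment_tensor(m)
  expect_lt(abs(sum(diag(tn))), 1e-10)
  expect_error(alignment_tensor(matrix(rnorm(9), 3, 3)), "symmetric")
  expect_error(alignment_tensor(diag(c(1, 1, 1)) * 1e-3), "traceless")
})

test_that("steric tensor distinguishes spheres from rods", {
  # near-spherical shell (deterministic spiral): negligible alignment
  n <- 200
  dirs <- 8 * rdcens:::fibonacci_sphere(n)
  ball <- conformer(data.frame(
    resno = 1L, resname = "G", chain = "A",
    atom = paste0("C", 1:n), elem = "C",
    x = dirs[, 1], y = dirs[, 2], z = dirs[, 3]))
  rod <- rod_conformer()
  s_ball <- steric_tensor(ball, "wall", orient_grid = 4000)
  s_rod <- steric_tensor(rod, "wall", orient_grid = 4000)
  expect_lt(norm(unclass(s_ball), "F"), 1e-3 * norm(unclass(s_rod), "F"))
  # rod: axially symmetric, unique axis along the rod
  pr <- tensor_principal(s_rod)
  expect_lt(pr$eta, 0.05)
  expect_gt(abs(pr$vectors[3, 3]), 0.999)
})

test_that("steric tensor matches a brute-force orientational average", {
  rod <- rod_conformer()
  s <- steric_tensor(rod, "wall", concentration = 0.022,
                     orient_grid = 8000)
  # independent oracle: direct formula on a dense latitude/longitude grid
  x <- coords(rod)
  x <- sweep(x, 2, colMeans(x))
  d <- 15 / sqrt(0.022)
  nth <- 200; nph <- 200
  th <- acos(seq(1 - 1 / nth, -1 + 1 / nth, length.out = nth))
  ph <- seq(0, 2 * pi * (1 - 1 / nph), length.out = nph)
  acc <- matrix(0, 3, 3); wsum <- 0
  for (t in th) {
    us <- cbind(sin(t) * cos(ph), sin(t) * sin(ph), cos(t))
    pr <- x %*% t(us)
    ext <- apply(pr, 2, function(v) max(v) - min(v))
    f <- pmax(1 - ext / d, 0)
    acc <- acc + crossprod(us * sqrt(f))
    wsum <- wsum + sum(f)
  }
  oracle <- (3 * acc / wsum - diag(3)) / 2
  expect_lt(norm(unclass(s) - oracle, "F") / norm(oracle, "F"), 0.01)
})

test_that("steric tensor is rotation-equivariant and rejects lines", {
  rod <- rod_conformer()
  s <- steric_tensor(rod, "rod", orient_grid = 5000)
  for (k in 1:3) {
    r <- rand_rot()
    s2 <- steric_tensor(transform_conformer(rod, r), "rod",
                        orient_grid = 5000)
    expect_lt(norm(unclass(s2) - r %*% unclass(s) %*% t(r), "F") /
                norm(unclass(s), "F"), 0.02)
  }
  line <- conformer(data.frame(
    resno = 1L, resname = "G", chain = "A", atom = paste0("C", 1:10),
    elem = "C", x = 0, y = 0, z = 1:10))
  expect_error(steric_tensor(line), "collinear")
})

test_that("predicted couplings follow the quadratic form exactly", {
  szz <- 1e-3
  tn <- alignment_tensor(diag(c(-szz / 2, -szz / 2, szz)))
  dmax <- bond_constants()$dmax_hz[bond_constants()$type == "CH"]
  magic <- acos(1 / sqrt(3))
  mk <- function(u) conformer(data.frame(
    resno = 1L, resname = "G", chain = "A",
    atom = c("C1'", "H1'", "N9", "C4"), elem = c("C", "H", "N", "C"),
    x = c(0, u[1], 5, 6), y = c(0, u[2], 5, 6), z = c(0, u[3], 5, 7)))
  ds <- rdc_dataset(data.frame(construct = "a", resno = 1, atom1 = "C1'",
                               atom2 = "H1'", rdc_hz = 0))
  expect_equal(predict_rdcs(mk(c(0, 0, 1.1)), tn, ds), dmax * szz,
               tolerance = 1e-12)
  u_magic <- 1.1 * c(sin(magic), 0, cos(magic))
  expect_lt(abs(predict_rdcs(mk(u_magic), tn, ds)), 1e-9 * abs(dmax))
  # traceless tensor: isotropic average vanishes like 1/sqrt(n)
  set.seed(8)
  nmc <- 20000
  us <- matrix(rnorm(3 * nmc), ncol = 3)
  us <- us / sqrt(rowSums(us^2))
  d <- dmax * rowSums((us %*% unclass(tn)) * us)
  expect_lt(abs(mean(d)), 3 * stats::sd(d) / sqrt(nmc))
  # missing atom is a named per-record error
  expect_error(predict_rdcs(mk(c(0, 0, 1.1)), tn, rdc_dataset(
    data.frame(construct = "a", resno = 1, atom1 = "C2'", atom2 = "H2'",
               rdc_hz = 0))), "C2'-H2'")
})

test_that("prediction is invariant under joint rotation of molecule and tensor", {
  h <- tar_like_helix()
  tn <- rdcens:::random_tensors(1)[[1]]
  ds <- rdc_dataset(data.frame(construct = "a", resno = rep(18:21, 2),
                               atom1 = rep(c("C1'", "C2'"), each = 4),
                               atom2 = rep(c("H1'", "H2'"), each = 4),
                               rdc_hz = 0))
  d0 <- predict_rdcs(h, tn, ds)
  r <- rand_rot()
  d1 <- predict_rdcs(transform_conformer(h, r, c(1, 2, 3)),
                     alignment_tensor(r %*% unclass(tn) %*% t(r)), ds)
  expect_equal(d0, d1, tolerance = 1e-9)
})

test_that("unsupported or duplicate records are rejected at load", {
  expect_error(rdc_dataset(data.frame(construct = "a", resno = 1,
                                      atom1 = "P", atom2 = "O5'",
                                      rdc_hz = 1)), "unsupported bond type")
  expect_error(rdc_dataset(data.frame(construct = "a", resno = c(1, 1),
                                      atom1 = "C1'", atom2 = "H1'",
                                      rdc_hz = c(1, 2))), "duplicate")
})

test_that("ensemble averaging is an equiprobable mean", {
  prob <- small_problem()
  m <- prob$mat
  expect_equal(ensemble_average(m, 3), m$values[3, ], tolerance = 1e-12)
  expect_equal(ensemble_average(m, c(4, 4)), m$values[4, ],
               tolerance = 1e-12)
  expect_equal(ensemble_average(m, c(1, 2)),
               (m$values[1, ] + m$values[2, ]) / 2, tolerance = 1e-12)
  expect_equal(ensemble_average(m, c(5, 9, 2)),
               ensemble_average(m, c(2, 5, 9)), tolerance = 1e-12)
  expect_error(ensemble_average(m, integer(0)), "empty")
  expect_error(ensemble_average(m, 10000), "outside")
})

test_that("scale factors are the least-squares minimizers", {
  prob <- small_problem()
  calc <- ensemble_average(prob$mat, prob$members)
  ds <- prob$ds
  ds$rdc_hz <- calc
  expect_equal(unname(fit_scale_factors(calc, ds)), rep(1, 3),
               tolerance = 1e-12)
  ds$rdc_hz <- 2 * calc
  expect_equal(unname(fit_scale_factors(calc, ds)), rep(2, 3),
               tolerance = 1e-12)
  # dense grid-search oracle on noisy data
  set.seed(21)
  ds$rdc_hz <- 1.3 * calc + rnorm(nrow(ds), 0, 2)
  l <- fit_scale_factors(calc, ds)
  for (j in unique(ds$construct)) {
    sel <- ds$construct == j
    grid <- seq(0.5, 2.5, by = 1e-4)
    sse <- vapply(grid, function(g)
      sum((g * calc[sel] - ds$rdc_hz[sel])^2), 0)
    expect_equal(unname(l[j]), grid[which.min(sse)], tolerance = 1e-4)
  }
  expect_error(fit_scale_factors(rep(0, nrow(ds)), ds), "degenerate")
  # optimality: fitted scales never do worse than unit scales
  expect_lte(rdc_rmsd(calc, ds, l), rdc_rmsd(calc, ds))
})

test_that("rdc rmsd matches its definition", {
  prob <- small_problem()
  calc <- ensemble_average(prob$mat, prob$members)
  ds <- prob$ds
  ds$rdc_hz <- calc
  one <- stats::setNames(rep(1, 3), unique(ds$construct))
  expect_equal(rdc_rmsd(calc, ds, one), 0, tolerance = 1e-12)
  ds$rdc_hz <- calc - 2
  expect_equal(rdc_rmsd(calc, ds, one), 2, tolerance = 1e-12)
  # independent direct evaluation on random data and scales
  set.seed(4)
  ds$rdc_hz <- rnorm(nrow(ds), 0, 10)
  l <- stats::setNames(runif(3, 0.5, 2), unique(ds$construct))
  direct <- sqrt(mean((unname(l[ds$construct]) * calc - ds$rdc_hz)^2))
  expect_equal(rdc_rmsd(calc, ds, l), direct, tolerance = 1e-12)
  sub <- ds$construct == "construct2"
  direct2 <- sqrt(mean((unname(l[ds$construct[sub]]) * calc[sub] -
                          ds$rdc_hz[sub])^2))
  expect_equal(rdc_rmsd(calc, ds, l, subset = sub), direct2,
               tolerance = 1e-12)
  expect_error(rdc_rmsd(calc, ds, l, subset = rep(FALSE, nrow(ds))),
               "empty")
})

test_that("svd tensor fitting inverts forward prediction exactly", {
  h <- tar_like_helix()
  set.seed(33)
  for (k in 1:5) {
    tn <- rdcens:::random_tensors(1)[[1]]
    ds <- rdc_dataset(data.frame(
      construct = "a",
      resno = rep(c(18:21, 41:44), each = 2),
      atom1 = rep(c("C1'", "C2'"), 8),
      atom2 = rep(c("H1'", "H2'"), 8),
      rdc_hz = 0))
    ds$rdc_hz <- predict_rdcs(h, tn, ds)
    fit <- fit_svd_tensor(ds, h)
    expect_lt(norm(unclass(fit$tensor) - unclass(tn), "F") /
                norm(unclass(tn), "F"), 1e-6)
    expect_lt(fit$rmsd_hz, 1e-9)
    expect_gt(fit$condition, 1)
  }
  expect_error(fit_svd_tensor(rdcens:::subset_dataset(ds, 1:4), h),
               "underdetermined")
  # parallel bond vectors are rank deficient even with >= 5 records
  ds_par <- rdc_dataset(data.frame(construct = "a", resno = 18:21,
                                   atom1 = "C1'", atom2 = "H1'",
                                   rdc_hz = 1))
  ds_par <- rbind(ds_par, ds_par[1, ])
  ds_par$resno[5] <- 41
  class(ds_par) <- c("rdc_dataset", "data.frame")
  expect_error(
    fit_svd_tensor(ds_par, conformer(data.frame(
      resno = rep(c(18:21, 41), each = 2),
      resname = "G", chain = "A",
      atom = rep(c("C1'", "H1'"), 5), elem = rep(c("C", "H"), 5),
      x = rep(seq(0, 20, 5), each = 2), y = 0,
      z = rep(c(0, 1.1), 5))), "underdetermined"))
})

test_that("precomputed matrices agree with standalone prediction and cache", {
  prob <- small_problem()
  sub <- prob$lib[1:3]
  ds <- rdcens:::subset_dataset(prob$ds, 1:10)
  mat <- precompute_matrix(sub, ds, mode = "fixed-tensor",
                           tensors = prob$tensors)
  expect_equal(dim(mat$values), c(3, 10))
  expect_true(all(is.finite(mat$values)))
  for (k in 1:3) {
    byhand <- numeric(10)
    for (j in unique(ds$construct)) {
      sel <- ds$construct == j
      byhand[sel] <- predict_rdcs(sub$conformers[[k]], prob$tensors[[j]],
                                  rdcens:::subset_dataset(ds, sel))
    }
    expect_equal(mat$values[k, ], byhand, tolerance = 1e-12)
  }
  cache <- tempfile("rdcmat")
  m1 <- precompute_matrix(sub, ds, mode = "fixed-tensor",
                          tensors = prob$tensors, cache_dir = cache)
  m2 <- precompute_matrix(sub, ds, mode = "fixed-tensor",
                          tensors = prob$tensors, cache_dir = cache)
  expect_identical(m1$values, m2$values)
  expect_length(list.files(cache), 1)
})

test_that("rdc tables round-trip through tsv", {
  prob <- small_problem()
  f <- tempfile(fileext = ".tsv")
  write_rdc_table(prob$ds, f)
  ds2 <- read_rdc_table(f)
  expect_equal(ds2$rdc_hz, prob$ds$rdc_hz, tolerance = 1e-9)
  expect_identical(ds2$construct, prob$ds$construct)
  expect_identical(ds2$pair_type, prob$ds$pair_type)
})
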