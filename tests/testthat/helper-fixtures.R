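# Shared fixtures, memoised so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

tar_like_helix <- function() memo("helix", {
  build_aform_helix(helix_spec("GCAG", "CUGC", 18:21, 41:44))
})

# Small synthetic problem shared by rdc / selection tests: 60-conformer
# library, 4-member truth, 3 constructs, noise-free couplings.
small_problem <- function() memo("small_problem", {
  model <- junction_model(seed = 101)
  lib <- generate_library(model, 60)
  set.seed(11)
  members <- sort(sample.int(60, 4))
  tensors <- rdcens:::random_tensors(3)
  truth <- simulated_truth(members, tensors, noise_sd = 0)
  ds <- simulate_rdc_dataset(lib, truth, 40, seed = 12)
  mat <- precompute_matrix(lib, ds, mode = "fixed-tensor", tensors = tensors)
  list(lib = lib, members = members, tensors = tensors, truth = truth,
       ds = ds, mat = mat, layout = attr(lib, "layout"))
})

# Independent quaternion (Horn) superposition oracle, used to cross-check
# the SVD-based implementation.
horn_rmsd <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  a <- sweep(x, 2, cx); b <- sweep(y, 2, cy)
  m <- crossprod(a, b)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  n4 <- matrix(c(
    sxx + syy + szz, syz - szy, szx - sxz, sxy - syx,
    syz - szy, sxx - syy - szz, sxy + syx, szx + sxz,
    szx - sxz, sxy + syx, -sxx + syy - szz, syz + szy,
    sxy - syx, szx + sxz, syz + szy, -sxx - syy + szz), 4, 4)
  lam <- max(eigen(n4, symmetric = TRUE)$values)
  msd <- (sum(a^2) + sum(b^2) - 2 * lam) / nrow(x)
  sqrt(max(0, msd))
}

# Random rotation matrix for invariance tests.
rand_rot <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

# n translated copies of a conformer with sequential model ids.
mk_lib <- function(h, n) {
  conformer_library(lapply(seq_len(n), function(k) {
    cf <- transform_conformer(h, diag(3), c(k, 0, 0))
    cf$model_id <- k
    cf
  }))
}

# A thin rod-like molecule (not perfectly collinear).
rod_conformer <- function(n = 40, length = 60, width = 0.4) {
  conformer(data.frame(
    resno = 1L, resname = "G", chain = "A",
    atom = paste0("C", seq_len(n)), elem = "C",
    x = rep(c(width, -width, 0, 0), length.out = n),
    y = rep(c(0, 0, width, -width), length.out = n),
    z = seq(-length / 2, length / 2, length.out = n)))
}
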