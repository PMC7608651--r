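# RDC prediction and fitting.
#
# A residual dipolar coupling for a bonded pair (i, j) is the quadratic form
# D = Dmax * u' S u of the unit bond vector u in the molecule's Saupe order
# matrix S (symmetric, traceless). S is predicted from molecular shape by a
# steric obstruction model, or fit to measured couplings by SVD. Ensemble
# RDCs are unweighted means over members; per-construct scale factors absorb
# differences in alignment magnitude between experiments.

#' Dipolar bond constants
#'
#' Maximal couplings and effective bond lengths for the supported bonded
#' atom-pair types. Only the ratios between pair types matter for ensemble
#' selection because per-construct scale factors rescale the overall
#' magnitude; the C-H value corresponds to the standard dipolar interaction
#' constant at an effective 1.104 A bond, N-H scaled by the gyromagnetic
#' ratios at 1.041 A.
#'
#' @return data.frame with columns `type`, `bond_length`, `dmax_hz`.
#' @export
bond_constants <- function() {
  data.frame(
    type = c("CH", "NH"),
    bond_length = c(1.104, 1.041),
    dmax_hz = c(24350, -11720),
    stringsAsFactors = FALSE)
}

pair_type <- function(atom1, atom2) {
  e1 <- substr(atom1, 1, 1)
  e2 <- substr(atom2, 1, 1)
  heavy <- ifelse(e1 == "H", e2, e1)
  hyd <- ifelse(e1 == "H", e1, e2)
  out <- paste0(heavy, hyd)
  out[!(e1 == "H" | e2 == "H") | !(heavy %in% c("C", "N"))] <- NA_character_
  out
}

#' Read an RDC table
#'
#' Canonical TSV schema: columns `construct`, `resno`, `atom1`, `atom2`,
#' `rdc_hz` and optional `error_hz` (default 2 Hz, the typical experimental
#' uncertainty). Records with unsupported bond types are rejected with a
#' named error, not skipped.
#'
#' @param path TSV file path.
#' @param default_error error assigned where `error_hz` is missing (Hz).
#' @return `rdc_dataset` data.frame.
#' @export
read_rdc_table <- function(path, default_error = 2.0) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  rdc_dataset(tab, default_error = default_error)
}

#' Construct an RDC dataset
#'
#' @param records data.frame with columns `construct`, `resno`, `atom1`,
#'   `atom2`, `rdc_hz`, optionally `error_hz`.
#' @param default_error per-record error used where none is given (Hz).
#' @return data.frame of class `rdc_dataset`.
#' @export
rdc_dataset <- function(records, default_error = 2.0) {
  req <- c("construct", "resno", "atom1", "atom2", "rdc_hz")
  stopifnot(is.data.frame(records), all(req %in% names(records)))
  records$atom1 <- normalise_atom_name(records$atom1)
  records$atom2 <- normalise_atom_name(records$atom2)
  if (is.null(records$error_hz)) records$error_hz <- default_error
  records$error_hz[is.na(records$error_hz)] <- default_error
  if (any(!is.finite(records$rdc_hz))) stop("non-finite RDC value")
  pt <- pair_type(records$atom1, records$atom2)
  if (any(is.na(pt))) {
    bad <- which(is.na(pt))[1]
    stop("unsupported bond type for record ", bad, ": ",
         records$atom1[bad], "-", records$atom2[bad],
         " (supported: bonded C-H and N-H pairs)")
  }
  key <- paste(records$construct, records$resno, records$atom1,
               records$atom2)
  if (anyDuplicated(key))
    stop("duplicate (construct, residue, atom pair) record: ",
         key[duplicated(key)][1])
  records$pair_type <- pt
  rownames(records) <- NULL
  class(records) <- c("rdc_dataset", "data.frame")
  records
}

#' Write an RDC dataset as TSV
#' @param dataset an `rdc_dataset`.
#' @param path output path.
#' @export
write_rdc_table <- function(dataset, path) {
  utils::write.table(
    dataset[, c("construct", "resno", "atom1", "atom2", "rdc_hz",
                "error_hz")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Alignment tensors

#' Construct an alignment (Saupe order) tensor
#'
#' @param m symmetric traceless 3x3 matrix of order parameters.
#' @param frame free-text note on the molecular frame.
#' @return object of class `alignment_tensor` (a 3x3 matrix).
#' @export
alignment_tensor <- function(m, frame = "molecular") {
  stopifnot(is.matrix(m), all(dim(m) == c(3, 3)))
  if (max(abs(m - t(m))) > 1e-8) stop("Saupe matrix must be symmetric")
  m <- (m + t(m)) / 2
  if (abs(sum(diag(m))) > 1e-8 * max(1, max(abs(m))))
    stop("Saupe matrix must be traceless")
  m <- m - diag(3) * sum(diag(m)) / 3
  structure(m, class = c("alignment_tensor", "matrix"), frame = frame)
}

#' Principal components of an alignment tensor
#'
#' Eigen-decomposition with |Szz| >= |Syy| >= |Sxx|; reports the axial
#' component Da-like magnitude `szz` and the asymmetry
#' eta = (Sxx - Syy)/Szz (conventions differ by sign pairing; here
#' eta = |(Syy - Sxx)/Szz|).
#'
#' @param tensor an [alignment_tensor()].
#' @return list with `values` (Sxx, Syy, Szz), `vectors` (columns), `eta`.
#' @export
tensor_principal <- function(tensor) {
  e <- eigen(unclass(tensor), symmetric = TRUE)
  o <- order(abs(e$values))  # |Sxx| <= |Syy| <= |Szz|
  vals <- e$values[o]
  vecs <- e$vectors[, o, drop = FALSE]
  eta <- abs((vals[2] - vals[1]) / vals[3])
  list(values = stats::setNames(vals, c("Sxx", "Syy", "Szz")),
       vectors = vecs, eta = eta)
}

#' Steric alignment tensor from molecular shape
#'
#' Obstruction-weighted orientational average: for each of `orient_grid`
#' near-uniform field directions u (deterministic Fibonacci grid), the
#' accessible fraction between planar barriers spaced `d` apart is
#' f(u) = max(0, 1 - l(u)/d), where l(u) is the molecule's heavy-atom extent
#' along u (`wall` medium) or its largest extent perpendicular to u
#' (`rod` medium, mimicking alignment by phage rods). The Saupe matrix is
#' S = <f (3 u u' - I)/2> / <f>. The barrier spacing is derived from the
#' medium concentration as d = 15/sqrt(c); at the typical phage
#' concentration 0.022 g/mL this gives roughly 100 A.
#'
#' @param conformer a [conformer()].
#' @param medium `"wall"` or `"rod"` obstruction geometry.
#' @param concentration medium concentration, g/mL.
#' @param orient_grid number of orientations averaged.
#' @return an [alignment_tensor()].
#' @export
steric_tensor <- function(conformer, medium = c("rod", "wall"),
                          concentration = 0.022, orient_grid = 5000) {
  medium <- match.arg(medium)
  x <- coords(conformer, heavy_sel(conformer))
  if (nrow(x) < 4) stop("need at least 4 heavy atoms")
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x)
  if (sv$d[2] < 1e-6 * sv$d[1])
    stop("degenerate (collinear) coordinates; steric shape undefined")
  u <- fibonacci_sphere(orient_grid)
  d_spacing <- 15 / sqrt(concentration)
  proj <- x %*% t(u)  # atoms x orientations
  if (medium == "wall") {
    ext <- apply(proj, 2, function(v) max(v) - min(v))
  } else {
    r2 <- rowSums(x^2)
    perp <- sqrt(pmax(r2 - proj^2, 0))
    ext <- 2 * apply(perp, 2, max)
  }
  f <- pmax(0, 1 - ext / d_spacing)
  if (sum(f) <= 0)
    stop("molecule larger than the barrier spacing in every orientation")
  a <- crossprod(u * sqrt(f))  # sum f u u'
  s <- (3 * a / sum(f) - diag(3)) / 2
  alignment_tensor(s, frame = sprintf("%s medium, %.4g g/mL", medium,
                                      concentration))
}

# ---------------------------------------------------------------------------
# Prediction and fitting

# Resolve record bond vectors in a conformer: unit vectors (n x 3).
bond_vectors <- function(conformer, dataset) {
  n <- nrow(dataset)
  out <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    a1 <- atom_xyz(conformer, dataset$resno[k], dataset$atom1[k])
    a2 <- atom_xyz(conformer, dataset$resno[k], dataset$atom2[k])
    if (is.null(a1) || is.null(a2))
      stop("missing atom for RDC record: residue ", dataset$resno[k],
           " ", dataset$atom1[k], "-", dataset$atom2[k],
           " not found in conformer ", conformer$model_id)
    out[k, ] <- unit(a2 - a1)
  }
  out
}

#' Predict RDCs for one conformer under a given alignment tensor
#'
#' D_k = Dmax(type_k) * u_k' S u_k for the unit bond vector u_k of record k.
#'
#' @param conformer a [conformer()].
#' @param tensor an [alignment_tensor()].
#' @param dataset an [rdc_dataset()] naming the bond vectors.
#' @param constants bond constants table, see [bond_constants()].
#' @return numeric vector of couplings (Hz), one per record.
#' @export
predict_rdcs <- function(conformer, tensor, dataset,
                         constants = bond_constants()) {
  u <- bond_vectors(conformer, dataset)
  dmax <- constants$dmax_hz[match(dataset$pair_type, constants$type)]
  if (any(is.na(dmax)))
    stop("no bond constants for pair type ",
         dataset$pair_type[which(is.na(dmax))[1]])
  s <- unclass(tensor)
  dmax * rowSums((u %*% s) * u)
}

#' Ensemble-average predicted RDCs
#'
#' Unweighted arithmetic mean over the selected members (equiprobable
#' conformers); duplicate indices count once per occurrence.
#'
#' @param matrix an [rdc_matrix()].
#' @param member_indices conformer indices (1-based library positions).
#' @return numeric vector of mean couplings per record (Hz).
#' @export
ensemble_average <- function(matrix, member_indices) {
  stopifnot(inherits(matrix, "rdc_matrix"))
  if (length(member_indices) == 0) stop("empty member list")
  if (any(member_indices < 1 | member_indices > nrow(matrix$values)))
    stop("member index outside library")
  colMeans(matrix$values[member_indices, , drop = FALSE])
}

#' Least-squares per-construct scale factors
#'
#' L_j = sum(Dexp * Dcalc) / sum(Dcalc^2) over the records of construct j:
#' the minimizer of the squared residuals (L_j Dcalc - Dexp)^2 for that
#' construct.
#'
#' @param calc predicted couplings, one per dataset record (Hz).
#' @param dataset the [rdc_dataset()].
#' @return named numeric vector of scale factors, one per construct.
#' @export
fit_scale_factors <- function(calc, dataset) {
  stopifnot(length(calc) == nrow(dataset))
  constructs <- unique(dataset$construct)
  out <- stats::setNames(numeric(length(constructs)), constructs)
  for (j in constructs) {
    i <- dataset$construct == j
    ss <- sum(calc[i]^2)
    if (ss <= 0)
      stop("degenerate scale fit: all predicted couplings zero for ",
           "construct ", j)
    out[j] <- sum(dataset$rdc_hz[i] * calc[i]) / ss
  }
  out
}

#' RDC root-mean-square deviation
#'
#' sqrt(mean((L_j Dcalc - Dexp)^2)) over the (optionally subset) records.
#'
#' @param calc predicted couplings, one per dataset record (Hz).
#' @param dataset the [rdc_dataset()].
#' @param scales named per-construct scale factors (default all 1).
#' @param subset optional logical or integer record filter.
#' @return RMSD in Hz.
#' @export
rdc_rmsd <- function(calc, dataset, scales = NULL, subset = NULL) {
  stopifnot(length(calc) == nrow(dataset))
  idx <- if (is.null(subset)) seq_len(nrow(dataset)) else
    seq_len(nrow(dataset))[subset]
  if (length(idx) == 0) stop("empty record subset")
  if (is.null(scales))
    scales <- stats::setNames(rep(1, length(unique(dataset$construct))),
                              unique(dataset$construct))
  l <- scales[dataset$construct[idx]]
  if (any(is.na(l)))
    stop("missing scale factor for construct ",
         dataset$construct[idx][which(is.na(l))[1]])
  sqrt(mean((l * calc[idx] - dataset$rdc_hz[idx])^2))
}

#' Fit a Saupe tensor to measured RDCs by SVD
#'
#' Solves D/Dmax = A s for the five independent Saupe elements
#' (Syy, Szz, Sxy, Sxz, Syz; Sxx = -Syy-Szz) with the standard
#' direction-cosine design matrix, via singular-value decomposition.
#'
#' @param dataset an [rdc_dataset()] (or subset) with >= 5 records.
#' @param conformer the [conformer()] providing the bond vectors.
#' @param constants bond constants table.
#' @return list with `tensor` ([alignment_tensor()]), `rmsd_hz`
#'   (back-calculated RMSD), `condition` (design condition number) and
#'   `calc` (back-calculated couplings).
#' @export
fit_svd_tensor <- function(dataset, conformer,
                           constants = bond_constants()) {
  n <- nrow(dataset)
  if (n < 5) stop("underdetermined: need >= 5 RDCs, got ", n)
  u <- bond_vectors(conformer, dataset)
  dmax <- constants$dmax_hz[match(dataset$pair_type, constants$type)]
  a <- cbind(u[, 2]^2 - u[, 1]^2,
             u[, 3]^2 - u[, 1]^2,
             2 * u[, 1] * u[, 2],
             2 * u[, 1] * u[, 3],
             2 * u[, 2] * u[, 3])
  b <- dataset$rdc_hz / dmax
  sv <- svd(a)
  tol <- max(dim(a)) * .Machine$double.eps * sv$d[1]
  if (sum(sv$d > tol) < 5)
    stop("underdetermined: design matrix rank ", sum(sv$d > tol), " < 5 ",
         "(bond vectors not linearly independent)")
  s5 <- sv$v %*% ((t(sv$u) %*% b) / sv$d)
  m <- matrix(c(-s5[1] - s5[2], s5[3], s5[4],
                s5[3], s5[1], s5[5],
                s5[4], s5[5], s5[2]), 3, 3)
  tensor <- alignment_tensor(m, frame = "SVD fit")
  calc <- dmax * rowSums((u %*% unclass(tensor)) * u)
  list(tensor = tensor,
       rmsd_hz = sqrt(mean((calc - dataset$rdc_hz)^2)),
       condition = sv$d[1] / sv$d[5],
       calc = calc)
}

# ---------------------------------------------------------------------------
# Precomputed conformer x record prediction matrices

#' Construct an RDC prediction matrix
#' @param values conformers x records matrix of predicted couplings (Hz).
#' @param dataset the [rdc_dataset()] the columns refer to.
#' @param conformer_ids library positions the rows refer to.
#' @return object of class `rdc_matrix`.
#' @export
rdc_matrix <- function(values, dataset, conformer_ids = seq_len(nrow(values))) {
  stopifnot(is.matrix(values), ncol(values) == nrow(dataset),
            nrow(values) == length(conformer_ids))
  if (any(!is.finite(values))) stop("missing entries in RDC matrix")
  structure(list(values = values, dataset = dataset,
                 conformer_ids = conformer_ids),
            class = "rdc_matrix")
}

#' Precompute per-conformer RDC predictions for a whole library
#'
#' In `steric` mode an alignment tensor is computed per conformer and per
#' construct from molecular shape (optionally after in-silico elongation of
#' that construct); in `fixed-tensor` mode the supplied per-construct
#' tensors are used directly (fast path; constructs then differ only through
#' their tensors, as experimental elongation differs through alignment).
#' Results can be cached on disk keyed by a content hash of the inputs.
#'
#' @param library a [conformer_library()].
#' @param dataset an [rdc_dataset()].
#' @param mode `"steric"` or `"fixed-tensor"`.
#' @param tensors named list of [alignment_tensor()] per construct
#'   (required for `fixed-tensor` mode).
#' @param medium,concentration,orient_grid steric-model settings.
#' @param elongation optional named list per construct:
#'   `list(terminal_bps =, n_bp =, seq_pattern =)` applied before the
#'   steric tensor is computed.
#' @param constants bond constants table.
#' @param cache_dir optional directory for the on-disk cache.
#' @return an [rdc_matrix()].
#' @export
precompute_matrix <- function(library, dataset,
                              mode = c("fixed-tensor", "steric"),
                              tensors = NULL, medium = "rod",
                              concentration = 0.022, orient_grid = 5000,
                              elongation = NULL,
                              constants = bond_constants(),
                              cache_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(library, "conformer_library"),
            inherits(dataset, "rdc_dataset"))
  constructs <- unique(dataset$construct)
  if (mode == "fixed-tensor") {
    if (is.null(tensors) || !all(constructs %in% names(tensors)))
      stop("fixed-tensor mode needs one tensor per construct")
  }
  key <- NULL
  if (!is.null(cache_dir)) {
    key <- content_hash(list(lapply(library$conformers, coords),
                             unclass(dataset), mode, tensors, medium,
                             concentration, orient_grid, elongation,
                             constants))
    cache_file <- file.path(cache_dir, paste0("rdcmat_", key, ".rds"))
    if (file.exists(cache_file)) {
      cached <- readRDS(cache_file)
      return(rdc_matrix(cached, dataset))
    }
  }
  nlib <- length(library$conformers)
  values <- matrix(NA_real_, nlib, nrow(dataset))
  # all conformers of a library share one atom layout, so record atom
  # indices are resolved once
  ref <- library$conformers[[1]]
  akey <- paste(ref$atoms$resno, ref$atoms$atom)
  i1 <- match(paste(dataset$resno, dataset$atom1), akey)
  i2 <- match(paste(dataset$resno, dataset$atom2), akey)
  if (any(is.na(i1)) || any(is.na(i2))) {
    bad <- which(is.na(i1) | is.na(i2))[1]
    stop("missing atom for RDC record: residue ", dataset$resno[bad], " ",
         dataset$atom1[bad], "-", dataset$atom2[bad])
  }
  dmax <- constants$dmax_hz[match(dataset$pair_type, constants$type)]
  for (i in seq_len(nlib)) {
    conf <- library$conformers[[i]]
    xyz <- coords(conf)
    u <- xyz[i2, , drop = FALSE] - xyz[i1, , drop = FALSE]
    u <- u / sqrt(rowSums(u^2))
    row <- numeric(nrow(dataset))
    for (j in constructs) {
      sel <- dataset$construct == j
      tensor_conf <- conf
      if (!is.null(elongation) && !is.null(elongation[[j]])) {
        e <- elongation[[j]]
        tensor_conf <- elongate_in_silico(conf, e$terminal_bps, e$n_bp,
                                          e$seq_pattern %||% "GC")
      }
      tn <- if (mode == "steric")
        steric_tensor(tensor_conf, medium, concentration, orient_grid)
      else tensors[[j]]
      us <- u[sel, , drop = FALSE]
      row[sel] <- dmax[sel] * rowSums((us %*% unclass(tn)) * us)
    }
    values[i, ] <- row
  }
  if (!is.null(key)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(values, file.path(cache_dir, paste0("rdcmat_", key, ".rds")))
  }
  rdc_matrix(values, dataset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Content hash via md5 of a serialised temp file (base R only).
content_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}
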