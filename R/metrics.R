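# Per-conformer and per-ensemble structural analytics: torsion angles and
# sugar pucker, chemical-shift pucker mapping, inter-helical Euler angles
# and bend categories, base stacking / extra-helical calls, flip
# cooperativity, and superposition-based ensemble distances.

#' Backbone, glycosidic and ring torsions per residue
#'
#' IUPAC-convention dihedrals (alpha, beta, gamma, delta, epsilon, zeta,
#' chi) plus the five endocyclic ring torsions, pseudorotation phase P and
#' amplitude nu_max. Missing atoms yield NA for the affected angles, never
#' an error.
#'
#' @param conf a [conformer()].
#' @return data.frame (class `torsion_set`) with one row per residue.
#' @export
compute_torsions <- function(conf) {
  at <- conf$atoms
  res <- unique(at[, c("chain", "resno", "resname")])
  res <- res[order(res$chain, res$resno), ]
  gx <- function(resno, atom) atom_xyz(conf, resno, atom)
  dih <- function(a, b, c, d) {
    if (is.null(a) || is.null(b) || is.null(c) || is.null(d))
      return(NA_real_)
    dihedral(a, b, c, d)
  }
  rows <- lapply(seq_len(nrow(res)), function(i) {
    r <- res$resno[i]
    ch <- res$chain[i]
    prev <- if (i > 1 && res$chain[i - 1] == ch) res$resno[i - 1] else NA
    nxt <- if (i < nrow(res) && res$chain[i + 1] == ch) res$resno[i + 1]
    else NA
    n_gly <- glyco_atom(res$resname[i])
    c_chi <- if (is_purine(res$resname[i])) "C4" else "C2"
    nu <- c(dih(gx(r, "C4'"), gx(r, "O4'"), gx(r, "C1'"), gx(r, "C2'")),
            dih(gx(r, "O4'"), gx(r, "C1'"), gx(r, "C2'"), gx(r, "C3'")),
            dih(gx(r, "C1'"), gx(r, "C2'"), gx(r, "C3'"), gx(r, "C4'")),
            dih(gx(r, "C2'"), gx(r, "C3'"), gx(r, "C4'"), gx(r, "O4'")),
            dih(gx(r, "C3'"), gx(r, "C4'"), gx(r, "O4'"), gx(r, "C1'")))
    ps <- if (all(is.finite(nu))) pseudorotation(nu)
    else list(P = NA_real_, nu_max = NA_real_)
    data.frame(
      chain = ch, resno = r, resname = res$resname[i],
      alpha = if (is.na(prev)) NA_real_ else
        dih(gx(prev, "O3'"), gx(r, "P"), gx(r, "O5'"), gx(r, "C5'")),
      beta = dih(gx(r, "P"), gx(r, "O5'"), gx(r, "C5'"), gx(r, "C4'")),
      gamma = dih(gx(r, "O5'"), gx(r, "C5'"), gx(r, "C4'"), gx(r, "C3'")),
      delta = dih(gx(r, "C5'"), gx(r, "C4'"), gx(r, "C3'"), gx(r, "O3'")),
      epsilon = if (is.na(nxt)) NA_real_ else
        dih(gx(r, "C4'"), gx(r, "C3'"), gx(r, "O3'"), gx(nxt, "P")),
      zeta = if (is.na(nxt)) NA_real_ else
        dih(gx(r, "C3'"), gx(r, "O3'"), gx(nxt, "P"), gx(nxt, "O5'")),
      chi = dih(gx(r, "O4'"), gx(r, "C1'"), gx(r, n_gly), gx(r, c_chi)),
      nu0 = nu[1], nu1 = nu[2], nu2 = nu[3], nu3 = nu[4], nu4 = nu[5],
      P = ps$P, nu_max = ps$nu_max)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("torsion_set", "data.frame")
  out
}

#' Classify the sugar pucker of one residue
#'
#' C2'-endo (South) iff the pseudorotation phase lies in `[90, 270)`
#' degrees, otherwise C3'-endo (North); puckers with amplitude below
#' `min_amplitude` are ambiguous. When the ring torsions are unavailable, a
#' delta-based fallback (C2'-endo iff delta > 100 degrees) can be used.
#'
#' @param tors a `torsion_set` from [compute_torsions()].
#' @param resno residue number.
#' @param min_amplitude amplitude floor (degrees) below which the call is
#'   ambiguous.
#' @param delta_fallback use delta when P is undefined.
#' @return list of class `pucker_call`: `state`, `P`, `amplitude`, `reason`.
#' @export
classify_pucker <- function(tors, resno, min_amplitude = 10,
                            delta_fallback = TRUE) {
  row <- tors[tors$resno == resno, ][1, ]
  state <- "ambiguous"
  reason <- ""
  if (is.finite(row$P) && is.finite(row$nu_max)) {
    if (abs(row$nu_max) < min_amplitude) {
      reason <- sprintf("amplitude %.1f below %.1f deg", abs(row$nu_max),
                        min_amplitude)
    } else {
      state <- if (row$P >= 90 && row$P < 270) "C2'-endo" else "C3'-endo"
    }
  } else if (delta_fallback && is.finite(row$delta)) {
    state <- if (row$delta > 100 && row$delta < 200) "C2'-endo" else
      "C3'-endo"
    reason <- "delta-based fallback (ring torsions incomplete)"
  } else {
    reason <- "pseudorotation undefined (incomplete ring)"
  }
  structure(list(state = state, P = row$P, amplitude = abs(row$nu_max),
                 reason = reason),
            class = "pucker_call")
}

#' Fraction of C2'-endo members at one residue
#'
#' Ambiguous members are excluded from the denominator and reported.
#'
#' @param ensemble list of [conformer()]s.
#' @param resno residue number present in all members.
#' @param ... passed to [classify_pucker()].
#' @return numeric fraction; attribute `n_ambiguous` counts exclusions.
#' @export
pucker_population <- function(ensemble, resno, ...) {
  calls <- vapply(ensemble, function(cf)
    classify_pucker(compute_torsions(cf), resno, ...)$state, "")
  usable <- calls != "ambiguous"
  if (!any(usable))
    stop("pucker population undefined: all ", length(calls),
         " members ambiguous at residue ", resno)
  out <- mean(calls[usable] == "C2'-endo")
  attr(out, "n_ambiguous") <- sum(!usable)
  out
}

#' Map a C1' chemical shift to a C2'-endo population
#'
#' Linear interpolation between the anchors 86 ppm (100% C2'-endo) and
#' 94 ppm (100% C3'-endo), clamped to `[0, 100]` by default.
#'
#' @param shift_ppm C1' chemical shift(s), ppm.
#' @param shift_c2endo,shift_c3endo anchor shifts, ppm.
#' @param clamp clamp the output into `[0, 100]`.
#' @return percent C2'-endo.
#' @export
shift_to_c2endo <- function(shift_ppm, shift_c2endo = 86,
                            shift_c3endo = 94, clamp = TRUE) {
  if (shift_c2endo == shift_c3endo) stop("anchor shifts must differ")
  pct <- 100 * (shift_c3endo - shift_ppm) / (shift_c3endo - shift_c2endo)
  if (clamp) pct <- pmin(100, pmax(0, pct))
  pct
}

# ---------------------------------------------------------------------------
# Inter-helical orientation

# Rotation mapping the idealized reference helix frame onto a helix segment
# of the conformer (heavy atoms, least squares).
helix_frame <- function(conf, bp_ranges, max_fit_rmsd = Inf) {
  # bp_ranges: list of length-2 integer vectors c(res_strand1, res_strand2)
  nm <- residue_names(conf)
  s1 <- vapply(bp_ranges, function(p) as.integer(p[1]), 1L)
  s2 <- vapply(bp_ranges, function(p) as.integer(p[2]), 1L)
  need <- as.character(c(s1, s2))
  if (!all(need %in% names(nm)))
    stop("helix range residues missing: ",
         paste(setdiff(need, names(nm)), collapse = ", "))
  spec <- helix_spec(paste(nm[as.character(s1)], collapse = ""),
                     paste(rev(nm[as.character(s2)]), collapse = ""),
                     strand1_numbers = s1, strand2_numbers = rev(s2),
                     allow_noncomplementary = TRUE)
  ref <- build_aform_helix(spec)
  src <- NULL; dst <- NULL
  for (r in c(s1, s2)) {
    ra <- ref$atoms[ref$atoms$resno == r & ref$atoms$elem != "H", ]
    ca <- conf$atoms[conf$atoms$resno == r & conf$atoms$elem != "H", ]
    common <- intersect(ra$atom, ca$atom)
    src <- rbind(src, as.matrix(ra[match(common, ra$atom),
                                   c("x", "y", "z")]))
    dst <- rbind(dst, as.matrix(ca[match(common, ca$atom),
                                   c("x", "y", "z")]))
  }
  fit <- kabsch(src, dst)
  fit$unreliable <- fit$rmsd > max_fit_rmsd
  fit
}

#' Inter-helical Euler angles of a two-helix junction
#'
#' Superposes an idealized A-form reference onto the upper and lower helix
#' segments (all heavy atoms of the given base pairs) and decomposes the
#' relative rotation R_upper R_lower' into ZYZ Euler angles, reported with
#' the sign convention in which a positive twist (alpha_h + gamma_h) is
#' over-twisting. `|beta_h|` is the inter-helical bend.
#'
#' @param conf a [conformer()].
#' @param upper_bps,lower_bps lists of base pairs (length-2 residue-number
#'   vectors, `c(strand1, strand2)`), at least 2 pairs each (3 recommended).
#' @param max_fit_rmsd superposition RMSD above which an `unreliable_frame`
#'   warning is attached.
#' @return list of class `interhelical_orientation`: `alpha_h`, `beta_h`,
#'   `gamma_h`, `bend`, `twist` (degrees), `fit_rmsd` (upper, lower),
#'   `unreliable` flag, and `rotation` (the relative rotation matrix).
#' @export
interhelical_euler <- function(conf, upper_bps, lower_bps,
                               max_fit_rmsd = 1.5) {
  stopifnot(length(upper_bps) >= 2, length(lower_bps) >= 2)
  up <- helix_frame(conf, upper_bps, max_fit_rmsd)
  lo <- helix_frame(conf, lower_bps, max_fit_rmsd)
  # upper-helix orientation expressed in the lower-helix frame; this form is
  # invariant under global rigid motion of the conformer
  rel <- t(lo$R) %*% up$R
  eu <- matrix_to_euler(rel)
  unreliable <- up$unreliable || lo$unreliable
  if (unreliable)
    warning(sprintf(paste0("unreliable helix frame: superposition RMSD ",
                           "%.2f / %.2f A exceeds %.2f A"),
                    up$rmsd, lo$rmsd, max_fit_rmsd))
  structure(c(eu, list(fit_rmsd = c(upper = up$rmsd, lower = lo$rmsd),
                       unreliable = unreliable, rotation = rel)),
            class = "interhelical_orientation")
}

#' Bend category of an inter-helical orientation
#'
#' Linear for `|beta_h| < 45` degrees, intermediate for 45-70, kinked above
#' 70; boundary values fall in the lower-bend class.
#'
#' @param orientation an `interhelical_orientation`, or a numeric bend in
#'   degrees.
#' @return one of "linear", "intermediate", "kinked".
#' @export
bend_category <- function(orientation) {
  bend <- if (is.numeric(orientation)) abs(orientation) else
    orientation$bend
  if (bend <= 45) "linear" else if (bend <= 70) "intermediate" else "kinked"
}

# ---------------------------------------------------------------------------
# Stacking, coaxiality and extra-helical calls

base_plane <- function(conf, resno) {
  nm <- residue_names(conf)[[as.character(resno)]]
  ring <- base_ring_atoms(nm)
  xyz <- t(vapply(ring, function(a) {
    v <- atom_xyz(conf, resno, a)
    if (is.null(v)) rep(NA_real_, 3) else v
  }, numeric(3)))
  if (any(!is.finite(xyz))) return(NULL)
  centre <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, centre))
  list(centre = centre, normal = sv$v[, 3])
}

#' Geometric base-stacking test
#'
#' Two bases stack when their ring centroids are within `max_dist`, their
#' plane normals within `max_angle` (unsigned), and the lateral centroid
#' offset perpendicular to the mean normal within `max_offset`.
#'
#' @param conf a [conformer()].
#' @param resno_a,resno_b residue numbers.
#' @param max_dist centroid distance cutoff (Angstrom).
#' @param max_angle normal angle cutoff (degrees).
#' @param max_offset lateral offset cutoff (Angstrom).
#' @return TRUE/FALSE, or NA when a base ring is incomplete.
#' @export
detect_stacking <- function(conf, resno_a, resno_b, max_dist = 4.5,
                            max_angle = 30, max_offset = 2.5) {
  pa <- base_plane(conf, resno_a)
  pb <- base_plane(conf, resno_b)
  if (is.null(pa) || is.null(pb)) return(NA)
  d <- pb$centre - pa$centre
  if (vnorm(d) > max_dist) return(FALSE)
  cosang <- abs(sum(pa$normal * pb$normal))
  if (acos(min(1, cosang)) / DEG > max_angle) return(FALSE)
  nb <- if (sum(pa$normal * pb$normal) < 0) -pb$normal else pb$normal
  n_mean <- unit(pa$normal + nb)
  lateral <- d - sum(d * n_mean) * n_mean
  vnorm(lateral) <= max_offset
}

#' Coaxial-stacking call for a junction conformer
#'
#' TRUE iff any configured cross-junction base pair of residues passes
#' [detect_stacking()] (for the classic two-helix bulge, the bridging pairs
#' are the closing pairs of the two helices).
#'
#' @param conf a [conformer()].
#' @param bridging_pairs non-empty list of length-2 residue-number vectors
#'   to test for stacking across the junction.
#' @param ... stacking thresholds passed to [detect_stacking()].
#' @return TRUE/FALSE (NA if all tested pairs were undetermined).
#' @export
detect_coaxial <- function(conf, bridging_pairs, ...) {
  if (length(bridging_pairs) == 0)
    stop("no bridging pairs configured")
  calls <- vapply(bridging_pairs, function(p) {
    stopifnot(length(p) == 2)
    detect_stacking(conf, p[1], p[2], ...)
  }, NA)
  if (any(calls %in% TRUE)) return(TRUE)
  if (all(is.na(calls))) return(NA)
  FALSE
}

#' Extra-helical (flipped-out) call for a bulge residue
#'
#' A residue is called extra-helical iff its base stacks with no base of
#' either closing base pair of the junction.
#'
#' @param conf a [conformer()].
#' @param resno the bulge residue.
#' @param flanking_bp_residues residue numbers of the closing base pairs
#'   (typically 4 residues).
#' @param ... stacking thresholds passed to [detect_stacking()].
#' @return TRUE/FALSE (NA when stacking was undetermined for all partners).
#' @export
detect_extra_helical <- function(conf, resno, flanking_bp_residues, ...) {
  calls <- vapply(flanking_bp_residues, function(r)
    detect_stacking(conf, resno, r, ...), NA)
  if (any(calls %in% TRUE)) return(FALSE)
  if (all(is.na(calls))) return(NA)
  TRUE
}

#' Cooperativity of simultaneous extra-helical flipping
#'
#' From per-conformer flip flags for the bulge nucleotides: the independent
#' flip-out probability of each nucleotide is estimated from conformers in
#' which the other nucleotides are flipped in,
#' P(out) = N(out | others in) / (N(out | others in) + N(all in)); the
#' no-cooperativity probability of all flipping out is the product of these;
#' and the cooperativity is -RT log(P_obs / P_indep) at T = 298 K (negative
#' for favourable cooperativity).
#'
#' @param flip_table logical matrix (conformers x nucleotides, usually 3
#'   columns) of extra-helical flags.
#' @param temperature Kelvin.
#' @return list of class `cooperativity_result`: `p_out` per nucleotide,
#'   `p_independent`, `p_observed`, `delta_g` (kcal/mol), `counts`.
#' @export
cooperativity <- function(flip_table, temperature = 298) {
  stopifnot(is.matrix(flip_table) || is.data.frame(flip_table))
  ft <- as.matrix(flip_table)
  if (any(is.na(ft))) stop("flip table contains undefined flags")
  mode(ft) <- "logical"
  n_nt <- ncol(ft)
  n_all_in <- sum(rowSums(ft) == 0)
  p_out <- numeric(n_nt)
  for (k in seq_len(n_nt)) {
    only_k <- sum(ft[, k] & rowSums(ft[, -k, drop = FALSE]) == 0)
    denom <- only_k + n_all_in
    if (denom == 0)
      stop("undefined flip probability for nucleotide ", k,
           ": no conformers with the other nucleotides flipped in ",
           "(N(out|others in) = ", only_k, ", N(all in) = ", n_all_in, ")")
    p_out[k] <- only_k / denom
  }
  p_indep <- prod(p_out)
  p_obs <- mean(rowSums(ft) == n_nt)
  r_gas <- 0.0019872041  # kcal / (mol K)
  delta_g <- if (p_indep > 0 && p_obs > 0)
    -r_gas * temperature * log(p_obs / p_indep)
  else NA_real_
  if (!is.finite(delta_g) && (p_indep == 0 || p_obs == 0))
    warning("cooperativity undefined: P_indep = ", signif(p_indep, 3),
            ", P_obs = ", signif(p_obs, 3))
  structure(list(p_out = p_out, p_independent = p_indep,
                 p_observed = p_obs, delta_g = delta_g,
                 counts = c(all_in = n_all_in, all_out = sum(
                   rowSums(ft) == n_nt), n = nrow(ft))),
            class = "cooperativity_result")
}

# ---------------------------------------------------------------------------
# Superposition RMSD and ensemble distances

match_selection <- function(mobile, reference, atom_selection = NULL) {
  sel_m <- if (is.null(atom_selection)) heavy_sel(mobile) else
    atom_selection(mobile$atoms)
  sel_r <- if (is.null(atom_selection)) heavy_sel(reference) else
    atom_selection(reference$atoms)
  am <- mobile$atoms[sel_m, ]
  ar <- reference$atoms[sel_r, ]
  key_m <- paste(am$chain, am$resno, am$atom)
  key_r <- paste(ar$chain, ar$resno, ar$atom)
  common <- intersect(key_m, key_r)
  if (length(common) < 3)
    stop("selections share fewer than 3 atoms")
  if (length(common) < length(key_m) || length(common) < length(key_r)) {
    extra <- c(setdiff(key_m, key_r), setdiff(key_r, key_m))
    if (length(extra) > 0 && length(common) < max(length(key_m),
                                                  length(key_r)))
      warning("unmatched atoms dropped: ",
              paste(utils::head(extra, 5), collapse = ", "),
              if (length(extra) > 5) " ..." else "")
  }
  list(x = as.matrix(am[match(common, key_m), c("x", "y", "z")]),
       y = as.matrix(ar[match(common, key_r), c("x", "y", "z")]))
}

#' Least-squares superposition RMSD
#'
#' Optimal rigid-body (rotation + translation) superposition of the mobile
#' conformer onto the reference over the matched atom selection (heavy
#' atoms by default, matched by chain/residue/atom name).
#'
#' @param mobile,reference [conformer()]s.
#' @param atom_selection NULL for all heavy atoms, or a function of the
#'   atom table returning a logical selection.
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(mobile, reference, atom_selection = NULL) {
  m <- match_selection(mobile, reference, atom_selection)
  kabsch(m$x, m$y)$rmsd
}

#' Lower-bound distance between two conformer ensembles
#'
#' For each conformer of A, the minimum superposition RMSD over B is found;
#' the root mean square of these values is taken, the procedure is repeated
#' from B, and the smaller of the two direction figures is returned — a
#' lower bound on how much the ensembles differ.
#'
#' @param a,b lists of [conformer()]s.
#' @param atom_selection as in [superpose_rmsd()].
#' @return distance in Angstrom; attribute `directions` holds both figures.
#' @export
ensemble_distance <- function(a, b, atom_selection = NULL) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  pair <- matrix(NA_real_, length(a), length(b))
  for (i in seq_along(a))
    for (j in seq_along(b))
      pair[i, j] <- superpose_rmsd(a[[i]], b[[j]], atom_selection)
  d_ab <- sqrt(mean(apply(pair, 1, min)^2))
  d_ba <- sqrt(mean(apply(pair, 2, min)^2))
  out <- min(d_ab, d_ba)
  attr(out, "directions") <- c(a_to_b = d_ab, b_to_a = d_ba)
  out
}
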