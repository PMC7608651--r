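# Idealized A-form helix construction.
#
# The duplex is generated from a rigid nucleotide template repeated by the
# helical screw symmetry (the classical fiber-model construction). The
# helical parameters (twist 32.7 deg/bp, rise 2.81 A/bp) follow fiber A-RNA;
# the remaining template geometry is a stylized idealized parameterization
# kept in one editable table. Sugar rings are built with an explicit
# pseudorotation phase so pucker analysis recovers the configured state.

#' Idealized A-form helix parameters
#'
#' One editable table of the geometry used by [build_aform_helix()] and the
#' synthetic generator. Twist and rise are the fiber-diffraction A-RNA
#' values; the remaining entries define the stylized template (C1' radius
#' and cross-pair span, the glycosidic swing angles, bond lengths, sugar
#' pseudorotation phases, and the backbone torsions tuned for inter-residue
#' O3'-P continuity).
#'
#' @return named list of parameters (degrees, Angstrom).
#' @export
aform_parameters <- function() {
  list(
    twist_deg = 32.7,        # helical twist per bp
    rise = 2.81,             # rise per bp along the axis
    c1_radius = 6.2,         # C1' distance from the helix axis
    c1_half_span = 5.2,      # half the cross-pair C1'-C1' distance (10.4 A)
    glyco_lambda_deg = 50,   # glycosidic swing off the cross-pair chord
    purine_swing_deg = 17,   # extra in-plane swing for purines, calibrated
                             # so purine and pyrimidine ring centroids share
                             # one azimuth (keeps mixed-sequence stacking)
    glyco_bond = 1.48,       # C1'-N glycosidic bond length
    chi_deg = -158,          # glycosidic torsion (anti)
    pucker_north_P = 18,     # pseudorotation phase, C3'-endo template
    pucker_south_P = 162,    # pseudorotation phase, C2'-endo template
    pucker_q = 0.38,         # ring puckering amplitude (A)
    # exocyclic backbone torsions of the template (O3' off the ring;
    # C5'/O5'/P chain off C4'), tuned for inter-residue O3'-P continuity
    t_o3 = -30, t_c5 = 80, t_o5 = -120, t_p = 65
  )
}

# --- sugar ring --------------------------------------------------------------

# Five-membered ring with a target Altona-Sundaralingam pseudorotation phase.
# Atoms in ring order O4', C1', C2', C3', C4'; built as a regular pentagon
# with out-of-plane displacements z_j = sqrt(2/5) q cos(phase + 4 pi j / 5),
# the pentagon phase calibrated numerically against the pseudorotation
# formula evaluated on the resulting torsions.
sugar_ring_raw <- function(phase_deg, q = 0.38, rp = 1.26) {
  j <- 0:4
  ang <- 2 * pi * j / 5
  z <- sqrt(2 / 5) * q * cos(phase_deg * DEG + 4 * pi * j / 5)
  m <- cbind(rp * cos(ang), rp * sin(ang), z)
  rownames(m) <- c("O4'", "C1'", "C2'", "C3'", "C4'")
  m
}

# Pseudorotation phase P (deg, [0, 360)) and amplitude nu_max from the five
# endocyclic torsions nu0..nu4.
pseudorotation <- function(nu) {
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  den <- 2 * nu[3] * (sin(36 * DEG) + sin(72 * DEG))
  P <- atan2(num, den) / DEG
  if (P < 0) P <- P + 360
  list(P = P, nu_max = nu[3] / cos(P * DEG))
}

ring_torsions <- function(m) {
  g <- function(n) m[n, ]
  c(nu0 = dihedral(g("C4'"), g("O4'"), g("C1'"), g("C2'")),
    nu1 = dihedral(g("O4'"), g("C1'"), g("C2'"), g("C3'")),
    nu2 = dihedral(g("C1'"), g("C2'"), g("C3'"), g("C4'")),
    nu3 = dihedral(g("C2'"), g("C3'"), g("C4'"), g("O4'")),
    nu4 = dihedral(g("C3'"), g("C4'"), g("O4'"), g("C1'")))
}

.template_cache <- new.env(parent = emptyenv())

# Pentagon phase that realises a target pseudorotation phase P.
calibrate_ring_phase <- function(P_target, q) {
  key <- sprintf("phase_%.3f_%.3f", P_target, q)
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  objective <- function(ph) {
    P <- pseudorotation(ring_torsions(sugar_ring_raw(ph, q)))$P
    d <- (P - P_target) %% 360
    min(d, 360 - d)
  }
  grid <- seq(0, 359, by = 2)
  vals <- vapply(grid, objective, 0)
  ph0 <- grid[which.min(vals)]
  opt <- stats::optimize(objective, interval = c(ph0 - 3, ph0 + 3))
  .template_cache[[key]] <- opt$minimum
  opt$minimum
}

sugar_ring <- function(P_target, q = 0.38) {
  sugar_ring_raw(calibrate_ring_phase(P_target, q), q)
}

# --- planar ring completion --------------------------------------------------

# Complete a regular planar n-ring from two adjacent placed vertices v1 -> v2
# (consecutive in ring order); `interior_hint` is a point on the ring side.
# Returns an n x 3 matrix of vertices in ring order starting at v1.
complete_ring <- function(v1, v2, n, interior_hint) {
  side <- vnorm(v2 - v1)
  apothem <- side / (2 * tan(pi / n))
  mid <- (v1 + v2) / 2
  edge <- unit(v2 - v1)
  # plane normal from the two anchors and the hint
  nrm <- unit(cross3(edge, interior_hint - v1))
  perp <- cross3(nrm, edge)  # in-plane, perpendicular to the edge
  if (sum(perp * (interior_hint - mid)) < 0) perp <- -perp
  centre <- mid + apothem * unit(perp)
  step <- 360 / n
  # rotation direction so that v1 rotated by one step lands on v2
  r1 <- v1 - centre
  for (s in c(1, -1)) {
    cand <- centre + as.vector(rot_axis(nrm, s * step) %*% r1)
    if (vnorm(cand - v2) < 1e-6 * side + 1e-3) {
      verts <- t(vapply(0:(n - 1), function(k)
        centre + as.vector(rot_axis(nrm, s * step * k) %*% r1),
        numeric(3)))
      attr(verts, "centre") <- centre
      attr(verts, "normal") <- nrm
      return(verts)
    }
  }
  stop("ring completion failed (anchors not consistent with a regular ring)")
}

# --- nucleotide templates ----------------------------------------------------

is_purine <- function(base) base %in% c("A", "G")

glyco_atom <- function(base) if (is_purine(base)) "N9" else "N1"

# Base ring atoms (used for stacking / plane computations).
base_ring_atoms <- function(base) {
  if (is_purine(base)) c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6")
  else c("N1", "C2", "N3", "C4", "C5", "C6")
}

# Build the base atoms given the sugar (needs C1', O4' and the glycosidic N
# already placed). Returns a named coordinate matrix including ring and
# exocyclic atoms, plus attributes anchoring the attachment frame.
build_base <- function(base, c1, o4, n_gly, chi) {
  out <- list()
  if (is_purine(base)) {
    c4 <- place_atom(o4, c1, n_gly, 1.37, 126, chi)
    c8 <- place_atom(c1, c4, n_gly, 1.37, 108, 180)
    pent <- complete_ring(n_gly, c8, 5, interior_hint = c4)
    rownames(pent) <- c("N9", "C8", "N7", "C5", "C4")
    c4 <- pent["C4", ]; c5 <- pent["C5", ]
    hexv <- complete_ring(c4, c5, 6,
                          interior_hint = 2 * ((c4 + c5) / 2) -
                            attr(pent, "centre"))
    rownames(hexv) <- c("C4", "C5", "C6", "N1", "C2", "N3")
    hex_c <- attr(hexv, "centre")
    pent_c <- attr(pent, "centre")
    out <- rbind(pent, hexv[c("C6", "N1", "C2", "N3"), ])
    exo <- rbind(
      H8 = pent["C8", ] + 1.08 * unit(pent["C8", ] - pent_c),
      if (base == "A") rbind(
        N6 = hexv["C6", ] + 1.34 * unit(hexv["C6", ] - hex_c),
        H2 = hexv["C2", ] + 1.08 * unit(hexv["C2", ] - hex_c))
      else rbind(
        O6 = hexv["C6", ] + 1.23 * unit(hexv["C6", ] - hex_c),
        N2 = hexv["C2", ] + 1.34 * unit(hexv["C2", ] - hex_c),
        H1 = hexv["N1", ] + 1.01 * unit(hexv["N1", ] - hex_c)))
    out <- rbind(out, exo)
    first_centre <- pent_c
  } else {
    c2 <- place_atom(o4, c1, n_gly, 1.38, 120, chi)
    c6 <- place_atom(c1, c2, n_gly, 1.38, 120, 180)
    hexv <- complete_ring(n_gly, c2, 6, interior_hint = c6)
    rownames(hexv) <- c("N1", "C2", "N3", "C4", "C5", "C6")
    hex_c <- attr(hexv, "centre")
    out <- hexv[c("N1", "C2", "N3", "C4", "C5", "C6"), ]
    exo <- rbind(
      O2 = hexv["C2", ] + 1.23 * unit(hexv["C2", ] - hex_c),
      H5 = hexv["C5", ] + 1.08 * unit(hexv["C5", ] - hex_c),
      H6 = hexv["C6", ] + 1.08 * unit(hexv["C6", ] - hex_c),
      if (base == "C") rbind(
        N4 = hexv["C4", ] + 1.34 * unit(hexv["C4", ] - hex_c))
      else rbind(
        O4 = hexv["C4", ] + 1.23 * unit(hexv["C4", ] - hex_c),
        H3 = hexv["N3", ] + 1.01 * unit(hexv["N3", ] - hex_c)))
    out <- rbind(out, exo)
    first_centre <- hex_c
  }
  # drop the duplicated glycosidic N row (already in the sugar block)
  out <- out[rownames(out) != glyco_atom(base), , drop = FALSE]
  attr(out, "first_ring_centre") <- first_centre
  out
}

#' Template nucleotide geometry
#'
#' Full heavy-atom nucleotide (phosphate through base, plus the protons the
#' supported RDC bond types need) in a local frame, with the configured sugar
#' pucker. Cached per (base, pucker).
#'
#' @param base one of "A", "C", "G", "U".
#' @param pucker "C3'-endo" (default) or "C2'-endo".
#' @param params parameter table from [aform_parameters()].
#' @return named coordinate matrix with attributes used for placement.
#' @keywords internal
nucleotide_template <- function(base, pucker = "C3'-endo",
                                params = aform_parameters()) {
  key <- paste0("nt_", base, "_", pucker, "_",
                paste(signif(unlist(params), 6), collapse = ","))
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  P <- if (pucker == "C2'-endo") params$pucker_south_P else
    params$pucker_north_P
  ring <- sugar_ring(P, params$pucker_q)
  g <- function(n) ring[n, ]
  # exocyclic sugar / backbone atoms; torsion signs fixed by the ring
  # construction's handedness (checked below)
  n_gly <- place_atom(g("C4'"), g("O4'"), g("C1'"), params$glyco_bond,
                      108, -122)
  h1p <- place_atom(g("C4'"), g("O4'"), g("C1'"), 1.09, 109, 119)
  o2p <- place_atom(g("O4'"), g("C1'"), g("C2'"), 1.41, 110, 120)
  h2p <- place_atom(g("O4'"), g("C1'"), g("C2'"), 1.09, 110, -120)
  o3p <- place_atom(g("C1'"), g("C2'"), g("C3'"), 1.42, 110, params$t_o3)
  h3p <- place_atom(g("C1'"), g("C2'"), g("C3'"), 1.09, 110,
                    params$t_o3 + 220)
  c5p <- place_atom(g("C2'"), g("C3'"), g("C4'"), 1.51, 116, params$t_c5)
  h4p <- place_atom(g("C2'"), g("C3'"), g("C4'"), 1.09, 110,
                    params$t_c5 + 120)
  o5p <- place_atom(g("C3'"), g("C4'"), c5p, 1.44, 110, params$t_o5)
  h5p <- place_atom(g("C3'"), g("C4'"), c5p, 1.09, 110, params$t_o5 + 120)
  h5pp <- place_atom(g("C3'"), g("C4'"), c5p, 1.09, 110, params$t_o5 - 120)
  p <- place_atom(g("C4'"), c5p, o5p, 1.60, 120, params$t_p)
  # the remaining tetrahedral slot around P faces the previous residue's O3'
  op1 <- place_atom(c5p, o5p, p, 1.49, 110, 55)
  op2 <- place_atom(c5p, o5p, p, 1.49, 110, 175)
  sugar <- rbind(ring,
                 "H1'" = h1p, "O2'" = o2p, "H2'" = h2p, "O3'" = o3p,
                 "H3'" = h3p, "C5'" = c5p, "H4'" = h4p, "O5'" = o5p,
                 "H5'" = h5p, "H5''" = h5pp, P = p, OP1 = op1, OP2 = op2)
  ngly_name <- glyco_atom(base)
  base_xyz <- build_base(base, g("C1'"), g("O4'"), n_gly, params$chi_deg)
  m <- rbind(sugar, matrix(n_gly, 1, 3, dimnames = list(ngly_name)),
             base_xyz)
  # attachment frame used to place the template into the helix; the
  # chi-defining ring atom provides a direction that is not collinear with
  # the glycosidic bond (the ring centre is, by construction)
  cfirst <- if (is_purine(base)) "C4" else "C2"
  d_hat <- unit(m[cfirst, ] - n_gly)
  g_hat <- unit(g("C1'") - n_gly)
  n_hat <- unit(cross3(d_hat, g_hat))  # base plane normal
  attr(m, "anchors") <- list(c1 = g("C1'"), n = n_gly, d_hat = d_hat,
                             g_hat = g_hat, n_hat = n_hat,
                             theta = angle3(g("C1'"), n_gly, m[cfirst, ]))
  .template_cache[[key]] <- m
  m
}

# --- helix assembly ----------------------------------------------------------

wc_partner <- c(A = "U", U = "A", G = "C", C = "G")

is_complementary <- function(b1, b2) {
  (wc_partner[[b1]] == b2) ||
    (b1 == "G" && b2 == "U") || (b1 == "U" && b2 == "G")
}

#' Helix specification
#'
#' @param strand1_seq,strand2_seq nucleotide strings, both 5' to 3'.
#' @param strand1_numbers,strand2_numbers residue numbers, one per
#'   nucleotide, in strand order.
#' @param allow_noncomplementary skip the Watson-Crick/wobble check.
#' @return object of class `helix_spec`.
#' @export
helix_spec <- function(strand1_seq, strand2_seq,
                       strand1_numbers = seq_len(nchar(strand1_seq)),
                       strand2_numbers = seq_len(nchar(strand2_seq)) +
                         nchar(strand1_seq),
                       allow_noncomplementary = FALSE) {
  s1 <- strsplit(toupper(strand1_seq), "")[[1]]
  s2 <- strsplit(toupper(strand2_seq), "")[[1]]
  if (length(s1) != length(s2))
    stop("strand lengths differ (", length(s1), " vs ", length(s2), ")")
  stopifnot(length(strand1_numbers) == length(s1),
            length(strand2_numbers) == length(s2))
  if (!all(c(s1, s2) %in% c("A", "C", "G", "U")))
    stop("sequences must be A/C/G/U")
  if (!allow_noncomplementary) {
    for (k in seq_along(s1)) {
      b2 <- s2[length(s2) + 1 - k]
      if (!is_complementary(s1[k], b2))
        stop("strands not reverse-complementary at pair ", k, " (",
             s1[k], "-", b2, "); set allow_noncomplementary to override")
    }
  }
  structure(list(s1 = s1, s2 = s2,
                 n1 = as.integer(strand1_numbers),
                 n2 = as.integer(strand2_numbers)),
            class = "helix_spec")
}

# Target anchor quadruplet for a nucleotide at base-pair slot 0,
# strand 1 (+y side) or strand 2 (-y side), matching the template's
# attachment frame exactly (congruent quads => exact rigid placement).
pair_frame_targets <- function(strand, theta, params = aform_parameters(),
                               purine = FALSE) {
  hs <- params$c1_half_span
  cx <- sqrt(params$c1_radius^2 - hs^2)
  sgn <- if (strand == 1) 1 else -1
  c1 <- c(cx, sgn * hs, 0)
  # glycosidic bond swings off the cross-pair chord toward the helix axis
  lam <- (params$glyco_lambda_deg +
            if (purine) params$purine_swing_deg else 0) * DEG
  u <- c(-sin(lam), -sgn * cos(lam), 0)
  n_t <- c1 + params$glyco_bond * u
  g_hat <- -u                                # N -> C1'
  partner_dir <- c(0, -sgn, 0)               # toward the paired base
  # in-plane direction of the chi-defining ring atom, at the template's
  # C1'-N-C(first) angle from the N -> C1' direction
  cand1 <- as.vector(rot_z(theta) %*% g_hat)
  cand2 <- as.vector(rot_z(-theta) %*% g_hat)
  d_hat <- if (sum(cand1 * partner_dir) >= sum(cand2 * partner_dir))
    cand1 else cand2
  list(c1 = c1, n = n_t, d_hat = d_hat, g_hat = g_hat)
}

# Rigid placement of a template nucleotide into base-pair slot `slot`
# (0-based) on `strand` (1 or 2); returns the transformed coordinate matrix.
place_nucleotide <- function(base, strand, slot, pucker = "C3'-endo",
                             params = aform_parameters()) {
  tmpl <- nucleotide_template(base, pucker, params)
  an <- attr(tmpl, "anchors")
  tg <- pair_frame_targets(strand, an$theta, params, is_purine(base))
  # chirality-consistent base normal for the target
  ct <- det(cbind(an$d_hat, an$g_hat, an$n_hat))
  z2 <- c(0, 0, 1)
  s <- if (det(cbind(tg$d_hat, tg$g_hat, z2)) * ct >= 0) 1 else -1
  src <- rbind(an$c1, an$n, an$n + an$d_hat, an$n + an$n_hat)
  dst <- rbind(tg$c1, tg$n, tg$n + tg$d_hat, tg$n + s * z2)
  fit <- kabsch(src, dst)
  xyz <- apply_rt(tmpl, fit$R, fit$t)
  screw <- rot_z(slot * params$twist_deg)
  sweep(xyz %*% t(screw), 2, c(0, 0, slot * params$rise), `+`)
}

nt_resnames <- c(A = "A", C = "C", G = "G", U = "U")

xyz_to_atoms <- function(xyz, resno, resname, chain) {
  data.frame(resno = as.integer(resno), resname = resname, chain = chain,
             atom = rownames(xyz), elem = substr(rownames(xyz), 1, 1),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build an idealized A-form duplex
#'
#' Constructs a double-stranded helix from a [helix_spec()] using the
#' parameters in [aform_parameters()]: base pair k (0-based, first pair of
#' strand 1) sits at rotation k x twist and translation k x rise along the
#' z axis; strand 2 is placed by the pair dyad. All standard heavy atoms are
#' present, plus the protons the supported RDC bond types require.
#'
#' @param spec a [helix_spec()].
#' @param pucker sugar pucker for every template ("C3'-endo" by default).
#' @param chains chain labels for strands 1 and 2.
#' @param params parameter table, see [aform_parameters()].
#' @return a [conformer()].
#' @export
build_aform_helix <- function(spec, pucker = "C3'-endo",
                              chains = c("A", "B"),
                              params = aform_parameters()) {
  stopifnot(inherits(spec, "helix_spec"))
  key <- paste0("helix_", paste(spec$s1, collapse = ""), "_",
                paste(spec$s2, collapse = ""), "_",
                paste(c(spec$n1, spec$n2), collapse = ","), "_", pucker,
                "_", paste(chains, collapse = ""), "_",
                paste(signif(unlist(params), 6), collapse = ","))
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  n <- length(spec$s1)
  blocks <- vector("list", 2 * n)
  for (k in seq_len(n)) {
    xyz <- place_nucleotide(spec$s1[k], strand = 1, slot = k - 1,
                            pucker = pucker, params = params)
    blocks[[k]] <- xyz_to_atoms(xyz, spec$n1[k], nt_resnames[[spec$s1[k]]],
                                chains[1])
  }
  for (j in seq_len(n)) {
    slot <- n - j  # strand 2 runs antiparallel
    xyz <- place_nucleotide(spec$s2[j], strand = 2, slot = slot,
                            pucker = pucker, params = params)
    blocks[[n + j]] <- xyz_to_atoms(xyz, spec$n2[j],
                                    nt_resnames[[spec$s2[j]]], chains[2])
  }
  out <- conformer(do.call(rbind, blocks), model_id = 1L)
  .template_cache[[key]] <- out
  out
}

#' Elongate a helix terminus with idealized A-form base pairs
#'
#' Appends `n_bp` idealized pairs coaxially to a helix terminus, leaving the
#' original coordinates untouched. The terminus is identified by its two
#' outermost base pairs (`terminal_bps`), used to anchor the extension by
#' least-squares superposition of an idealized reference duplex; this mimics
#' the in-silico elongation applied to experimentally elongated constructs
#' before RDC prediction.
#'
#' @param conf a [conformer()].
#' @param terminal_bps list of two length-2 integer vectors
#'   `c(resno_strand1, resno_strand2)`: the outermost pair first, then the
#'   pair just inside it.
#' @param n_bp number of pairs to append (0 returns the input unchanged).
#' @param seq_pattern recycled strand-1 sequence for the added pairs
#'   (default alternating "GC"); strand 2 takes the complement.
#' @param max_fit_rmsd superposition RMSD (Angstrom) above which the
#'   terminus is rejected as not a paired A-form region.
#' @return a [conformer()] with `2 * n_bp` added residues (numbered above
#'   the existing maximum, chain labels preserved per strand).
#' @export
elongate_in_silico <- function(conf, terminal_bps, n_bp,
                               seq_pattern = "GC", max_fit_rmsd = 2.0) {
  stopifnot(inherits(conf, "conformer"), n_bp >= 0)
  if (n_bp == 0) return(conf)
  stopifnot(is.list(terminal_bps), length(terminal_bps) == 2)
  outer_bp <- terminal_bps[[1]]
  inner_bp <- terminal_bps[[2]]
  nm <- residue_names(conf)
  need <- as.character(c(outer_bp, inner_bp))
  if (!all(need %in% names(nm)))
    stop("terminal base-pair residues not found: ",
         paste(setdiff(need, names(nm)), collapse = ", "))
  s1_seq <- paste0(nm[[as.character(inner_bp[1])]],
                   nm[[as.character(outer_bp[1])]])
  s2_seq <- paste0(nm[[as.character(outer_bp[2])]],
                   nm[[as.character(inner_bp[2])]])
  pat <- strsplit(toupper(seq_pattern), "")[[1]]
  add1 <- pat[((seq_len(n_bp) - 1) %% length(pat)) + 1]
  add2 <- unname(wc_partner[add1])
  ntot <- 2 + n_bp
  # The terminus may run in either slot direction relative to strand-1
  # numbering, so build both reference orientations (extension above the
  # outer pair, or below it) and keep the one that superposes better.
  make_ref <- function(direction) {
    if (direction == "up") {
      spec <- helix_spec(
        paste0(s1_seq, paste(add1, collapse = "")),
        paste0(paste(rev(add2), collapse = ""), s2_seq),
        allow_noncomplementary = TRUE)
      ids <- list(inner1 = 1, outer1 = 2, inner2 = 2 * ntot,
                  outer2 = 2 * ntot - 1,
                  ext1 = function(k) 2 + k,
                  ext2 = function(k) 2 * ntot - 1 - k)
    } else {
      spec <- helix_spec(
        paste0(paste(rev(add1), collapse = ""),
               substr(s1_seq, 2, 2), substr(s1_seq, 1, 1)),
        paste0(substr(s2_seq, 2, 2), substr(s2_seq, 1, 1),
               paste(add2, collapse = "")),
        allow_noncomplementary = TRUE)
      ids <- list(inner1 = ntot, outer1 = ntot - 1, inner2 = ntot + 1,
                  outer2 = ntot + 2,
                  ext1 = function(k) n_bp + 1 - k,
                  ext2 = function(k) ntot + 2 + k)
    }
    list(ref = build_aform_helix(spec), ids = ids)
  }
  anchor_fit <- function(cand) {
    pairs <- rbind(
      c(cand$ids$outer1, outer_bp[1]), c(cand$ids$inner1, inner_bp[1]),
      c(cand$ids$outer2, outer_bp[2]), c(cand$ids$inner2, inner_bp[2]))
    src <- NULL; dst <- NULL
    for (r in seq_len(nrow(pairs))) {
      ra <- cand$ref$atoms[cand$ref$atoms$resno == pairs[r, 1] &
                             cand$ref$atoms$elem != "H", ]
      ca <- conf$atoms[conf$atoms$resno == pairs[r, 2] &
                         conf$atoms$elem != "H", ]
      common <- intersect(ra$atom, ca$atom)
      if (length(common) < 3)
        stop("too few matching heavy atoms in residue ", pairs[r, 2])
      src <- rbind(src, as.matrix(ra[match(common, ra$atom),
                                     c("x", "y", "z")]))
      dst <- rbind(dst, as.matrix(ca[match(common, ca$atom),
                                     c("x", "y", "z")]))
    }
    kabsch(src, dst)
  }
  cands <- lapply(c("up", "down"), make_ref)
  fits <- lapply(cands, anchor_fit)
  pick <- which.min(c(fits[[1]]$rmsd, fits[[2]]$rmsd))
  ref <- cands[[pick]]$ref
  ids <- cands[[pick]]$ids
  fit <- fits[[pick]]
  if (fit$rmsd > max_fit_rmsd)
    stop(sprintf(paste0("terminus does not superpose on an idealized ",
                        "A-form pair step (RMSD %.2f A > %.2f A); ",
                        "is it a paired region?"), fit$rmsd, max_fit_rmsd))
  base_no <- max(conf$atoms$resno)
  ch1 <- conf$atoms$chain[conf$atoms$resno == outer_bp[1]][1]
  ch2 <- conf$atoms$chain[conf$atoms$resno == outer_bp[2]][1]
  new_blocks <- list()
  for (k in seq_len(n_bp)) {
    a1 <- ref$atoms[ref$atoms$resno == ids$ext1(k), ]
    a1$resno <- as.integer(base_no + k)
    a1$chain <- ch1
    a2 <- ref$atoms[ref$atoms$resno == ids$ext2(k), ]
    a2$resno <- as.integer(base_no + n_bp + k)
    a2$chain <- ch2
    new_blocks[[k]] <- rbind(a1, a2)
  }
  new_atoms <- do.call(rbind, new_blocks)
  new_atoms[, c("x", "y", "z")] <-
    apply_rt(as.matrix(new_atoms[, c("x", "y", "z")]), fit$R, fit$t)
  conformer(rbind(conf$atoms, new_atoms), model_id = conf$model_id,
            energy = conf$energy)
}
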