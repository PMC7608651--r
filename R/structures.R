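# Conformer containers and multi-model PDB I/O.
#
# A conformer is a single atomic model; a conformer library is an ordered
# collection of models sharing one sequence and residue numbering (the pool
# that ensemble selection draws from). Coordinates are Angstrom, residue
# numbers are kept verbatim from the source file and never renumbered.

#' Construct a conformer
#'
#' @param atoms data.frame with columns `resno` (integer), `resname`
#'   (A/C/G/U, possibly with modification flags appended), `chain`, `atom`
#'   (PDB-convention name, primes written as `'`), `elem`, `x`, `y`, `z`.
#' @param model_id integer model identifier.
#' @param energy optional score (arbitrary units; Rosetta energy units when
#'   imported from a structure-prediction run).
#' @return object of class `conformer`.
#' @export
conformer <- function(atoms, model_id = 1L, energy = NA_real_) {
  req <- c("resno", "resname", "chain", "atom", "elem", "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(req %in% names(atoms)))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in conformer")
  if (any(!nzchar(atoms$atom))) stop("empty atom name")
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate atom names within a residue: ",
         key[duplicated(key)][1])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, model_id = as.integer(model_id),
                 energy = energy),
            class = "conformer")
}

# Fast internal constructor: skips validation for atom tables already known
# to be well-formed (e.g. the synthetic generator's fixed layout).
new_conformer <- function(atoms, model_id = 1L, energy = NA_real_) {
  structure(list(atoms = atoms, model_id = as.integer(model_id),
                 energy = energy),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer> model %d: %d residues, %d atoms%s\n",
              x$model_id, length(unique(paste(x$atoms$chain, x$atoms$resno))),
              nrow(x$atoms),
              if (is.finite(x$energy)) sprintf(", energy %.2f", x$energy)
              else ""))
  invisible(x)
}

#' Coordinate matrix of a conformer
#' @param conf a [conformer()].
#' @param sel optional row selection on the atom table.
#' @return n x 3 matrix (Angstrom).
#' @export
coords <- function(conf, sel = TRUE) {
  as.matrix(conf$atoms[sel, c("x", "y", "z"), drop = FALSE])
}

set_coords <- function(conf, xyz, sel = TRUE) {
  conf$atoms[sel, c("x", "y", "z")] <- xyz
  conf
}

heavy_sel <- function(conf) conf$atoms$elem != "H"

#' Coordinates of one named atom
#' @param conf a [conformer()].
#' @param resno residue number.
#' @param atom atom name (primes as `'`).
#' @param chain optional chain filter.
#' @return numeric 3-vector, or NULL if absent.
#' @export
atom_xyz <- function(conf, resno, atom, chain = NULL) {
  i <- which(conf$atoms$resno == resno & conf$atoms$atom == atom &
               (if (is.null(chain)) TRUE else conf$atoms$chain == chain))
  if (length(i) == 0) return(NULL)
  as.numeric(conf$atoms[i[1], c("x", "y", "z")])
}

residue_names <- function(conf) {
  a <- conf$atoms[!duplicated(paste(conf$atoms$chain, conf$atoms$resno)), ]
  stats::setNames(a$resname, a$resno)
}

#' Construct a conformer library
#'
#' @param conformers list of [conformer()] objects sharing residue indexing.
#' @param sequence optional nucleotide string; derived from the first
#'   conformer when missing.
#' @param source free-text provenance.
#' @return object of class `conformer_library`.
#' @export
conformer_library <- function(conformers, sequence = NULL, source = "") {
  stopifnot(is.list(conformers), length(conformers) >= 1)
  ref <- conformers[[1]]
  ref_key <- paste(ref$atoms$chain, ref$atoms$resno, ref$atoms$atom)
  for (k in seq_along(conformers)) {
    key <- paste(conformers[[k]]$atoms$chain, conformers[[k]]$atoms$resno,
                 conformers[[k]]$atoms$atom)
    if (length(key) != length(ref_key) || any(key != ref_key))
      stop("model ", conformers[[k]]$model_id,
           " has a different residue/atom set than model ", ref$model_id)
  }
  if (is.null(sequence))
    sequence <- paste(residue_names(ref), collapse = "")
  structure(list(conformers = conformers, sequence = sequence,
                 source = source),
            class = "conformer_library")
}

#' @export
print.conformer_library <- function(x, ...) {
  cat(sprintf("<conformer_library> %d conformers, sequence %s (%s)\n",
              length(x$conformers), x$sequence,
              if (nzchar(x$source)) x$source else "unspecified source"))
  invisible(x)
}

#' @export
length.conformer_library <- function(x) length(x$conformers)

#' @export
`[.conformer_library` <- function(x, i) {
  conformer_library(x$conformers[i], sequence = x$sequence,
                    source = x$source)
}

# ---------------------------------------------------------------------------
# PDB I/O (multi-model), delegated to bio3d with a thin normalisation layer.

normalise_atom_name <- function(x) gsub("\\*", "'", x)

#' Read a (multi-model) PDB file into a conformer library
#'
#' One conformer per MODEL record (a single conformer for files without
#' MODEL records). Residue numbers, names and chains are preserved verbatim;
#' primes in atom names are accepted as `'` or `*` and normalised to `'`.
#' Per-model energies are read from `REMARK ENERGY <model> <value>` lines
#' when present.
#'
#' @param path PDB file path.
#' @param model_range optional integer vector of model indices to keep
#'   (positions in file order, 1-based).
#' @return a [conformer_library()].
#' @export
read_models <- function(path, model_range = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("unparseable PDB file ", path,
                                           ": ", conditionMessage(e)))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  if (n_models == 0) stop("no models found in ", path)
  at <- pdb$atom
  template <- data.frame(
    resno = as.integer(at$resno),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    atom = normalise_atom_name(trimws(at$elety)),
    stringsAsFactors = FALSE)
  template$elem <- substr(template$atom, 1, 1)
  energies <- read_energy_remarks(path)
  keep <- if (is.null(model_range)) seq_len(n_models) else model_range
  if (any(keep < 1 | keep > n_models))
    stop("model_range outside 1..", n_models)
  confs <- lapply(keep, function(m) {
    v <- xyz[m, ]
    atoms <- template
    atoms$x <- v[seq(1, length(v), 3)]
    atoms$y <- v[seq(2, length(v), 3)]
    atoms$z <- v[seq(3, length(v), 3)]
    conformer(atoms, model_id = m,
              energy = if (!is.null(energies) && m <= length(energies))
                energies[m] else NA_real_)
  })
  conformer_library(confs, source = path)
}

read_energy_remarks <- function(path) {
  ln <- grep("^REMARK\\s+ENERGY\\s", readLines(path, warn = FALSE),
             value = TRUE)
  if (length(ln) == 0) return(NULL)
  parts <- do.call(rbind, strsplit(trimws(ln), "\\s+"))
  ids <- as.integer(parts[, 3])
  vals <- as.numeric(parts[, 4])
  out <- rep(NA_real_, max(ids))
  out[ids] <- vals
  out
}

#' Write a conformer library as a multi-model PDB file
#'
#' MODEL ids are written sequentially from 1. Atom-name primes are written
#' as `'`. Per-model energies, when present, are emitted as
#' `REMARK ENERGY <model> <value>` lines so they round-trip through
#' [read_models()].
#'
#' @param library a [conformer_library()].
#' @param path output file path.
#' @export
write_models <- function(library, path) {
  stopifnot(inherits(library, "conformer_library"))
  if (length(library$conformers) == 0) stop("empty library")
  ref <- library$conformers[[1]]$atoms
  xyz <- do.call(rbind, lapply(library$conformers, function(cf)
    as.vector(t(as.matrix(cf$atoms[, c("x", "y", "z")])))))
  ok <- tryCatch({
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = ref$resno, resid = ref$resname,
                     elety = ref$atom, chain = ref$chain,
                     chainter = FALSE)
    TRUE
  }, error = function(e) stop("cannot write PDB file ", path, ": ",
                              conditionMessage(e)))
  energies <- vapply(library$conformers, function(cf) cf$energy, 0)
  if (any(is.finite(energies))) {
    remarks <- sprintf("REMARK ENERGY %d %.6f",
                       which(is.finite(energies)),
                       energies[is.finite(energies)])
    writeLines(c(remarks, readLines(path, warn = FALSE)), path)
  }
  invisible(path)
}

#' Attach per-model energies to a library
#'
#' @param library a [conformer_library()].
#' @param energies numeric vector (one per conformer) or the path of a TSV
#'   sidecar with columns `model_id` and `energy`.
#' @return the library with energies set.
#' @export
set_energies <- function(library, energies) {
  if (is.character(energies)) {
    tab <- utils::read.delim(energies, header = TRUE)
    stopifnot(all(c("model_id", "energy") %in% names(tab)))
    e <- rep(NA_real_, length(library$conformers))
    ids <- vapply(library$conformers, function(cf) cf$model_id, 1L)
    m <- match(ids, tab$model_id)
    e[!is.na(m)] <- tab$energy[m[!is.na(m)]]
    energies <- e
  }
  stopifnot(length(energies) == length(library$conformers))
  for (k in seq_along(energies))
    library$conformers[[k]]$energy <- energies[k]
  library
}

#' Filter a conformer library by energy and sub-sample it
#'
#' Keeps conformers with `energy < energy_cutoff`, then, if more than
#' `target_size` survive, draws `target_size` of them uniformly without
#' replacement. Deterministic for a given `seed`.
#'
#' @param library a [conformer_library()].
#' @param energy_cutoff score cutoff; conformers must carry energies unless
#'   the cutoff is `Inf`.
#' @param target_size maximum library size after sampling.
#' @param seed integer RNG seed for the sub-sampling draw.
#' @return filtered [conformer_library()].
#' @export
filter_library <- function(library, energy_cutoff = Inf,
                           target_size = length(library$conformers),
                           seed = 1L) {
  stopifnot(inherits(library, "conformer_library"))
  if (is.finite(energy_cutoff)) {
    e <- vapply(library$conformers, function(cf) cf$energy, 0)
    if (any(!is.finite(e)))
      stop("finite energy cutoff requires energies on every conformer ",
           "(missing for model ",
           library$conformers[[which(!is.finite(e))[1]]]$model_id, ")")
    keep <- which(e < energy_cutoff)
  } else {
    keep <- seq_along(library$conformers)
  }
  if (length(keep) == 0)
    stop("no conformers survive the energy cutoff (0 of ",
         length(library$conformers), ")")
  if (length(keep) > target_size) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    keep <- sort(sample(keep, target_size))
  }
  out <- library[keep]
  out$source <- paste0(library$source, " [filtered]")
  out
}

# Preserve the caller's RNG state around internally seeded draws.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Apply a rigid motion to a conformer
#'
#' @param conf a [conformer()].
#' @param R 3x3 rotation matrix.
#' @param t translation 3-vector (Angstrom).
#' @return the transformed [conformer()].
#' @export
transform_conformer <- function(conf, R = diag(3), t = c(0, 0, 0)) {
  set_coords(conf, apply_rt(coords(conf), R, t))
}
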