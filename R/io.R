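# Structure and observable containers plus file I/O. Coordinates are stored
# in angstrom (PDB native); residue numbering is 1-based and ranges are
# inclusive, matching the usual "residues 14-20" style.

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

#' Peptide conformer
#'
#' A single peptide structure: an n x 3 coordinate matrix plus per-atom
#' metadata. The unit of all ensemble statistics.
#'
#' @param xyz n x 3 numeric matrix of Cartesian coordinates (angstrom).
#' @param atom Data frame with one row per atom and columns `elety` (atom
#'   name, e.g. "CA"), `resno` (1-based residue index), `resid` (3-letter
#'   residue name), `chain` (chain id) and optionally `elesy` (element
#'   symbol, derived from the atom name when absent).
#' @return An object of class `conformer`.
#' @export
conformer <- function(xyz, atom) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) == nrow(atom))
  if (!all(is.finite(xyz))) stop("conformer coordinates must be finite")
  need <- c("elety", "resno", "resid", "chain")
  miss <- setdiff(need, names(atom))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  atom <- as.data.frame(atom, stringsAsFactors = FALSE)
  if (is.null(atom$elesy)) atom$elesy <- substr(gsub("[0-9]", "", atom$elety), 1, 1)
  # residue indices must be contiguous within each chain
  for (ch in unique(atom$chain)) {
    r <- unique(atom$resno[atom$chain == ch])
    if (length(r) > 1 && !all(diff(sort(r)) == 1))
      stop("residue indices not contiguous in chain ", ch)
  }
  dimnames(xyz) <- NULL
  structure(list(xyz = xyz, atom = atom), class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat("Conformer:", nrow(x$xyz), "atoms,",
      length(unique(paste(x$atom$chain, x$atom$resno))), "residues,",
      length(unique(x$atom$chain)), "chain(s)\n")
  invisible(x)
}

#' Which residues have a complete backbone
#'
#' @param c A [conformer].
#' @return Named logical vector over residues (chain.resno): TRUE when N,
#'   CA and C are all present.
#' @export
backbone_complete <- function(c) {
  key <- paste(c$atom$chain, c$atom$resno, sep = ".")
  vapply(split(c$atom$elety, key)[unique(key)],
         function(e) all(c("N", "CA", "C") %in% e), logical(1))
}

# Atom-index selection helpers -------------------------------------------

# Logical index over atoms for a named selection; hydrogens are excluded
# from every geometric selection (the analyses are heavy-atom level).
atom_selection <- function(atom, selection = c("calpha", "backbone", "heavy", "all")) {
  selection <- match.arg(selection)
  hyd <- atom$elesy == "H"
  switch(selection,
         calpha = atom$elety == "CA",
         backbone = atom$elety %in% c("N", "CA", "C") & !hyd,
         heavy = !hyd,
         all = rep(TRUE, nrow(atom)))
}

#' Conformational ensemble
#'
#' An ordered collection of conformers sharing one topology, standing in
#' for trajectory frames.
#'
#' @param conformers List of [conformer] objects with identical atom count
#'   and ordering.
#' @param labels Optional frame labels (e.g. time or state).
#' @return An object of class `ensemble` with elements `atom` (shared
#'   topology), `xyz` (frames x 3n matrix, bio3d layout) and `labels`.
#' @export
ensemble <- function(conformers, labels = NULL) {
  stopifnot(length(conformers) >= 1)
  atom <- conformers[[1]]$atom
  n <- nrow(atom)
  for (cf in conformers) {
    if (nrow(cf$atom) != n || !identical(cf$atom$elety, atom$elety))
      stop("all ensemble members must share atom count and ordering")
  }
  xyz <- t(vapply(conformers, function(cf) as.numeric(t(cf$xyz)), numeric(3 * n)))
  if (!is.null(labels) && length(labels) != length(conformers))
    stop("labels length must equal the number of frames")
  structure(list(atom = atom, xyz = xyz, labels = labels), class = "ensemble")
}

#' Number of frames in an ensemble
#' @param ens An [ensemble].
#' @return Integer frame count.
#' @export
n_frames <- function(ens) nrow(ens$xyz)

#' Extract one frame of an ensemble as a conformer
#' @param ens An [ensemble].
#' @param i Frame index (1-based).
#' @return A [conformer].
#' @export
get_conformer <- function(ens, i) {
  stopifnot(i >= 1, i <= n_frames(ens))
  conformer(matrix(ens$xyz[i, ], ncol = 3, byrow = TRUE), ens$atom)
}

# frame coordinates as an n x 3 matrix
frame_xyz <- function(ens, i) matrix(ens$xyz[i, ], ncol = 3, byrow = TRUE)

#' Read a structure file into an ensemble
#'
#' Multi-model PDB files are read with one conformer per MODEL record
#' (bio3d backend); XYZ files with one conformer per frame. Coordinates in
#' angstrom, atom order preserved.
#'
#' @param path Input file path.
#' @param format `"pdb"` (multi-model) or `"xyz"`.
#' @return An [ensemble].
#' @export
read_structures <- function(path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") read_pdb_ensemble(path) else read_xyz_ensemble(path)
}

read_pdb_ensemble <- function(path) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE, verbose = FALSE),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  atom <- data.frame(elety = pdb$atom$elety,
                     resno = pdb$atom$resno,
                     resid = pdb$atom$resid,
                     chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
                     elesy = ifelse(is.na(pdb$atom$elesy) | pdb$atom$elesy == "",
                                    substr(gsub("[0-9]", "", pdb$atom$elety), 1, 1),
                                    pdb$atom$elesy),
                     stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(atom))
    stop("topology error in '", path, "': inconsistent atom counts across models")
  confs <- lapply(seq_len(nrow(xyz)), function(i)
    conformer(matrix(xyz[i, ], ncol = 3, byrow = TRUE), atom))
  ensemble(confs)
}

read_xyz_ensemble <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) <= length(lines)]
  confs <- list()
  i <- 1
  natoms <- NA
  while (i <= length(lines)) {
    if (grepl("^\\s*$", lines[i])) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("XYZ parse error at line ", i, ": expected atom count")
    if (is.na(natoms)) natoms <- n
    if (n != natoms)
      stop("topology error in '", path, "': inconsistent atom counts across frames")
    if (i + 1 + n > length(lines)) stop("XYZ parse error: truncated frame at line ", i)
    body <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4)
    if (length(bad)) stop("XYZ parse error at line ", i + 1 + bad[1],
                          ": need element and three coordinates")
    el <- vapply(parts, `[`, character(1), 1)
    xyz <- t(vapply(parts, function(p)
      suppressWarnings(as.numeric(p[2:4])), numeric(3)))
    if (!all(is.finite(xyz))) stop("XYZ parse error: non-numeric coordinate near line ", i)
    atom <- data.frame(elety = el, resno = seq_len(n),
                       resid = "UNK", chain = "A", elesy = el,
                       stringsAsFactors = FALSE)
    confs[[length(confs) + 1]] <- conformer(xyz, atom)
    i <- i + 2 + n
  }
  if (!length(confs)) stop("no frames found in '", path, "'")
  ensemble(confs)
}

#' Write an ensemble (or single conformer) to file
#'
#' Multi-frame ensembles are written as multi-model PDB (MODEL/ENDMDL
#' framing) or concatenated XYZ frames.
#'
#' @param ens An [ensemble] or [conformer].
#' @param path Output path.
#' @param format `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_structures <- function(ens, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (inherits(ens, "conformer")) ens <- ensemble(list(ens))
  stopifnot(inherits(ens, "ensemble"), n_frames(ens) >= 1)
  if (format == "pdb") {
    multi <- n_frames(ens) > 1
    ok <- tryCatch({
      bio3d::write.pdb(file = path, xyz = if (multi) ens$xyz else ens$xyz[1, ],
                       resno = ens$atom$resno, resid = ens$atom$resid,
                       elety = ens$atom$elety, chain = ens$atom$chain,
                       elesy = ens$atom$elesy)
      TRUE
    }, error = function(e) stop("I/O error writing '", path, "': ",
                                conditionMessage(e), call. = FALSE))
    if (!multi) {
      # keep MODEL/ENDMDL framing even for a single frame
      lines <- readLines(path)
      first <- which(grepl("^(ATOM|HETATM)", lines))[1]
      last <- max(which(grepl("^(ATOM|HETATM|TER)", lines)))
      lines <- c(lines[seq_len(first - 1)], "MODEL        1",
                 lines[first:last], "ENDMDL",
                 if (last < length(lines)) lines[(last + 1):length(lines)])
      writeLines(lines, path)
    }
  } else {
    con <- tryCatch(file(path, "w"),
                    error = function(e) stop("I/O error opening '", path, "'",
                                             call. = FALSE))
    on.exit(close(con))
    for (i in seq_len(n_frames(ens))) {
      xyz <- frame_xyz(ens, i)
      writeLines(as.character(nrow(xyz)), con)
      writeLines(paste("frame", i), con)
      writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                         ens$atom$elesy, xyz[, 1], xyz[, 2], xyz[, 3]), con)
    }
  }
  invisible(path)
}

# Observable tables -------------------------------------------------------

#' Per-residue observable table
#'
#' Residue-indexed experimental or back-calculated observables: J-couplings
#' (Hz), chemical shifts (ppm) or secondary-structure propensities
#' (dimensionless).
#'
#' @param residue Integer residue indices (1-based, unique).
#' @param value Numeric values; `NA` marks an explicitly missing entry.
#' @param kind One of `"jcoupling"`, `"shift"`, `"propensity"`.
#' @param nucleus Optional nucleus label for shifts (e.g. `"CA"`, `"CB"`).
#' @param provenance Free-text provenance label.
#' @return A data frame of class `observable_table`.
#' @export
observable_table <- function(residue, value, kind = "shift",
                             nucleus = NULL, provenance = "") {
  residue <- as.integer(residue)
  if (anyDuplicated(residue)) stop("duplicate residue index in observable table")
  if (any(!is.finite(value) & !is.na(value)))
    stop("observable values must be finite or NA")
  out <- data.frame(residue = residue, value = as.numeric(value))
  class(out) <- c("observable_table", "data.frame")
  attr(out, "kind") <- kind
  attr(out, "nucleus") <- nucleus
  attr(out, "provenance") <- provenance
  out
}

#' Read a delimited observable table
#'
#' Expects a header line `residue<TAB>value` (comma-separated accepted);
#' empty value fields are preserved as missing.
#'
#' @param path Input file.
#' @param kind Observable kind (see [observable_table]).
#' @param nucleus Optional nucleus label.
#' @return An [observable_table].
#' @export
read_observables <- function(path, kind = c("jcoupling", "shift", "propensity"),
                             nucleus = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1)
  sep <- if (grepl("\t", hdr)) "\t" else if (grepl(",", hdr)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!all(c("residue", "value") %in% names(tab)))
    stop("observable file must have 'residue' and 'value' columns")
  observable_table(tab$residue, tab$value, kind = kind, nucleus = nucleus,
                   provenance = path)
}

#' Write an observable table as TSV
#' @param tab An [observable_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observables <- function(tab, path) {
  utils::write.table(tab[, c("residue", "value")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
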