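# Molecule container and structure file I/O (PDB via bio3d; PDBQT and
# XYZ via small dedicated readers). Coordinates are Angstroms in the
# source frame; nothing is re-centered on load.

KNOWN_ELEMENTS <- c("H", "C", "N", "O", "F", "P", "S", "CL", "BR", "I",
                    "NA", "MG", "K", "CA", "FE", "ZN", "MN", "CU", "SE", "B")

# AutoDock atom types -> element symbols (PDBQT column 78+).
AD_TYPE_MAP <- c(A = "C", C = "C", N = "N", NA. = "N", OA = "O", O = "O",
                 SA = "S", S = "S", HD = "H", H = "H", HS = "H", F = "F",
                 CL = "Cl", BR = "Br", I = "I", P = "P")

#' Construct a molecule from an atom table
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `name`, `resid`, `resno`, `chain`, `is_polar_h`.
#' @param label free-text label.
#' @return object of class `molecule` (a data.frame of atoms).
#' @export
new_molecule <- function(atoms, label = "") {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  needed <- c("element", "x", "y", "z")
  if (!all(needed %in% names(atoms)))
    stop("atom table needs columns ", paste(needed, collapse = ", "))
  if (any(!is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("non-finite coordinates", call. = FALSE)
  bad <- !toupper(atoms$element) %in% KNOWN_ELEMENTS
  if (any(bad))
    stop("unrecognized element symbol: ", atoms$element[which(bad)[1L]],
         call. = FALSE)
  for (opt in c("name", "resid", "resno", "chain"))
    if (is.null(atoms[[opt]])) atoms[[opt]] <- NA
  if (is.null(atoms$is_polar_h)) atoms$is_polar_h <- FALSE
  structure(atoms, label = label, class = c("molecule", "data.frame"))
}

#' Coordinates of a molecule as an n x 3 matrix
#' @param mol a `molecule`.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(mol) {
  as.matrix(as.data.frame(mol)[c("x", "y", "z")])
}

#' @export
print.molecule <- function(x, ...) {
  lab <- attr(x, "label")
  cat("Molecule", if (nzchar(lab)) paste0("'", lab, "'"), "-", nrow(x),
      "atoms (", paste(names(sort(table(x$element), decreasing = TRUE)),
                       collapse = " "), ")\n")
  invisible(x)
}

# Canonical element capitalization ("CL" -> "Cl").
canonical_element <- function(el) {
  el <- toupper(trimws(el))
  paste0(substr(el, 1, 1), tolower(substr(el, 2, nchar(el))))
}

#' Read a 3D structure file
#'
#' Supports PDB (read with bio3d, residue labels retained), PDBQT
#' (AutoDock dialect; the AD atom type supplies the element and marks
#' polar hydrogens) and XYZ. Multi-model PDBQT files yield the model
#' selected by `model`.
#'
#' @param path structure file; format from the extension unless given.
#' @param format one of "auto", "pdb", "pdbqt", "xyz".
#' @param model model number for multi-model files (default 1).
#' @param strip_waters drop HOH/WAT residues (default TRUE).
#' @return a `molecule`: data.frame of atoms with columns `element`,
#'   `x`, `y`, `z`, `name`, `resid`, `resno`, `chain`, `is_polar_h`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "pdbqt", "xyz"),
                           model = 1L, strip_waters = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     pdb = "pdb", pdbqt = "pdbqt", ent = "pdb", xyz = "xyz",
                     stop("cannot infer structure format from: ", path,
                          call. = FALSE))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         pdb = read_pdb_structure(path, strip_waters),
         pdbqt = read_pdbqt_structure(path, model, strip_waters),
         xyz = read_xyz_structure(path))
}

read_pdb_structure <- function(path, strip_waters) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (strip_waters) at <- at[!at$resid %in% c("HOH", "WAT", "DOD"), ]
  if (nrow(at) == 0L) stop("no atoms in ", path, call. = FALSE)
  el <- at$elesy
  miss <- is.na(el) | el == ""
  if (any(miss)) el[miss] <- substr(gsub("[0-9 ]", "", at$elety[miss]), 1, 1)
  atoms <- data.frame(element = canonical_element(el),
                      x = at$x, y = at$y, z = at$z,
                      name = at$elety, resid = at$resid, resno = at$resno,
                      chain = at$chain, stringsAsFactors = FALSE)
  new_molecule(atoms, label = basename(path))
}

read_pdbqt_structure <- function(path, model, strip_waters) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 0L) {
    if (model > length(model_starts))
      stop("requested model ", model, " but file has ",
           length(model_starts), call. = FALSE)
    ends <- grep("^ENDMDL", lines)
    lines <- lines[model_starts[model]:ends[model]]
  }
  idx <- grep("^(ATOM|HETATM)", lines)
  if (length(idx) == 0L) stop("no ATOM/HETATM records in ", path,
                              call. = FALSE)
  rec <- lines[idx]
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(rec, from, to)))
    if (anyNA(v))
      stop("malformed ", what, " field at line ", idx[which(is.na(v))[1L]],
           " of ", basename(path), call. = FALSE)
    v
  }
  x <- num(31, 38, "x"); y <- num(39, 46, "y"); z <- num(47, 54, "z")
  adtype <- toupper(trimws(substr(rec, 78, 80)))
  el <- AD_TYPE_MAP[adtype]
  if (anyNA(el)) {
    # fall back to the atom-name column for nonstandard types
    guess <- substr(gsub("[0-9 ]", "", substr(rec, 13, 16)), 1, 1)
    el[is.na(el)] <- guess[is.na(el)]
  }
  atoms <- data.frame(element = canonical_element(el), x = x, y = y, z = z,
                      name = trimws(substr(rec, 13, 16)),
                      resid = trimws(substr(rec, 18, 20)),
                      resno = suppressWarnings(as.integer(substr(rec, 23, 26))),
                      chain = trimws(substr(rec, 22, 22)),
                      is_polar_h = adtype == "HD",
                      stringsAsFactors = FALSE)
  if (strip_waters) atoms <- atoms[!atoms$resid %in% c("HOH", "WAT"), ]
  new_molecule(atoms, label = basename(path))
}

read_xyz_structure <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("empty or truncated XYZ file: ", path,
                               call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n)) stop("malformed XYZ atom count at line 1", call. = FALSE)
  body <- lines[3:(2 + n)]
  parts <- strsplit(trimws(body), "[[:space:]]+")
  bad <- which(vapply(parts, length, 1L) < 4L)
  if (length(bad) > 0L)
    stop("malformed XYZ record at line ", bad[1L] + 2L, call. = FALSE)
  el <- vapply(parts, `[[`, "", 1L)
  xyz <- vapply(parts, function(p) suppressWarnings(as.numeric(p[2:4])),
                numeric(3))
  if (anyNA(xyz)) {
    bad <- which(apply(xyz, 2, anyNA))[1L]
    stop("malformed coordinate field at line ", bad + 2L, call. = FALSE)
  }
  atoms <- data.frame(element = canonical_element(el),
                      x = xyz[1, ], y = xyz[2, ], z = xyz[3, ],
                      stringsAsFactors = FALSE)
  new_molecule(atoms, label = basename(path))
}

#' Write a molecule as XYZ
#' @param mol a `molecule`.
#' @param path output path.
#' @param comment second-line comment.
#' @return the path, invisibly.
#' @export
write_xyz <- function(mol, path, comment = attr(mol, "label")) {
  m <- as.data.frame(mol)
  write_atomic(function(tmp) {
    con <- file(tmp, "w"); on.exit(close(con))
    writeLines(c(as.character(nrow(m)), comment), con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                       m$element, m$x, m$y, m$z), con)
  }, path)
}

#' Write a molecule as minimal PDB
#' @param mol a `molecule`; residue fields used when present.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pdb <- function(mol, path) {
  m <- as.data.frame(mol)
  resid <- ifelse(is.na(m$resid), "UNK", m$resid)
  resno <- ifelse(is.na(m$resno), 1L, m$resno)
  chain <- ifelse(is.na(m$chain) | m$chain == "", "A", m$chain)
  name <- ifelse(is.na(m$name), m$element, m$name)
  write_atomic(function(tmp) {
    lines <- sprintf(
      "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(m)), substr(name, 1, 4), " ", substr(resid, 1, 3),
      chain, as.integer(resno), " ", m$x, m$y, m$z, 1, 0,
      toupper(m$element))
    writeLines(c(lines, "END"), tmp)
  }, path)
}
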