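# Docking post-processing: affinity tables and the -8 kcal/mol hit
# filter, pose RMSD with optional Kabsch superposition, and geometric
# contact / hydrogen-bond detection. Docking itself is never run here;
# its outputs are consumed as inputs.

#' Docking box metadata
#'
#' The grid-box definition used for the estrogen-receptor screen,
#' carried for provenance in reports; nothing here executes docking.
#'
#' @return list with `center` and `size` (Angstroms).
#' @export
docking_box <- function() {
  list(center = c(x = 29.944, y = -1.861, z = 24.611),
       size = c(x = 18, y = 14, z = 18))
}

#' Read a docking affinity table
#'
#' TSV/CSV with columns `ligand` and `affinity_kcal_mol` (aliases
#' accepted). For AutoDock-Vina-style output, see [read_vina_result()].
#'
#' @param path table path.
#' @return data.frame with `ligand`, `affinity` (kcal/mol).
#' @export
read_affinity_table <- function(path) {
  df <- read_table_auto(path)
  lig <- match_column(df, c("ligand", "name", "name_of_the_ligand", "compound"))
  aff <- match_column(df, c("affinity_kcal_mol", "affinity", "binding_affinity"))
  if (is.null(lig) || is.null(aff))
    stop("affinity table needs ligand and affinity columns", call. = FALSE)
  aff <- suppressWarnings(as.numeric(gsub("−", "-", as.character(aff))))
  if (anyNA(aff)) stop("non-numeric affinity in row ",
                       which(is.na(aff))[1L], call. = FALSE)
  data.frame(ligand = as.character(lig), affinity = aff,
             stringsAsFactors = FALSE)
}

#' Extract binding affinities from a Vina-style result file
#'
#' Parses `REMARK VINA RESULT:` records (docked PDBQT output) or the
#' mode table of a log file; one affinity per docked mode.
#'
#' @param path file path.
#' @param ligand ligand name (defaults to the file stem).
#' @return data.frame with `ligand`, `mode`, `affinity`.
#' @export
read_vina_result <- function(path, ligand = tools::file_path_sans_ext(basename(path))) {
  lines <- readLines(path)
  hits <- regmatches(lines, regexpr("VINA RESULT:\\s*(-?[0-9.]+)", lines))
  if (length(hits) > 0L) {
    aff <- as.numeric(sub(".*:\\s*", "", hits))
  } else {
    tab <- grep("^\\s*[0-9]+\\s+-?[0-9.]+\\s", lines, value = TRUE)
    if (length(tab) == 0L) stop("no Vina result records in ", path,
                                call. = FALSE)
    aff <- vapply(strsplit(trimws(tab), "\\s+"),
                  function(p) as.numeric(p[2L]), 0)
  }
  data.frame(ligand = ligand, mode = seq_along(aff), affinity = aff,
             stringsAsFactors = FALSE)
}

#' Filter docking hits by binding affinity
#'
#' Keeps records with affinity less than or equal to the threshold
#' (more negative = stronger; the boundary value is included). Names in
#' `exclude` (case-insensitive) are removed first, e.g. to set aside
#' the co-crystallized reference ligand.
#'
#' @param records data.frame with `ligand`, `affinity`.
#' @param threshold kcal/mol cutoff (default -8).
#' @param exclude optional character vector of ligand names to drop.
#' @return filtered data.frame, input order preserved.
#' @examples
#' tab <- read_affinity_table(system.file("extdata", "vina_affinities.tsv",
#'                                        package = "phytodock"))
#' filter_hits(tab, exclude = "Hydroxytamoxifen")$ligand
#' @export
filter_hits <- function(records, threshold = -8, exclude = NULL) {
  stop_if_not_number(records$affinity, "affinity")
  stop_if_not_number(threshold, "threshold")
  if (!is.null(exclude))
    records <- records[!tolower(records$ligand) %in% tolower(exclude), ,
                       drop = FALSE]
  records[records$affinity <= threshold, , drop = FALSE]
}

#' Normalize compound-name spellings
#'
#' Docking tables and chromatogram tables sometimes spell the same
#' compound differently ("Limonenel", "Copaane"). Known variants are
#' mapped to canonical spellings and matches against an optional
#' reference list are done on a punctuation-insensitive key. Changed
#' entries are flagged in the `changed` attribute.
#'
#' @param x character vector of compound names.
#' @param reference optional character vector of canonical names; when
#'   a key match is found the reference spelling is returned.
#' @return character vector, with logical attribute `changed`.
#' @export
normalize_compound_names <- function(x, reference = NULL) {
  aliases <- c(limonenel = "Limonene", copaane = "Copaene",
               cryophyllene = "Caryophyllene",
               `cryophyllene oxide` = "Caryophyllene oxide",
               hydroxycaryophyllene = "14-Hydroxy-9-epi-(E)-caryophyllene")
  # drop "<...>" qualifier annotations, then punctuation, for matching
  key <- function(s) gsub("[^a-z0-9]", "", tolower(gsub("<[^>]*>", "", s)))
  out <- x
  hit <- tolower(trimws(x)) %in% names(aliases)
  out[hit] <- aliases[tolower(trimws(x[hit]))]
  if (!is.null(reference)) {
    m <- match(key(out), key(reference))
    out[!is.na(m)] <- reference[m[!is.na(m)]]
  }
  structure(out, changed = out != x)
}

#' RMSD between two poses of the same molecule
#'
#' Atoms are matched by file order and must present the same element
#' sequence. With `superimpose = TRUE` the optimal least-squares rigid
#' rotation (Kabsch) is applied first, giving the minimal attainable
#' RMSD; otherwise deviations are measured in place, as when comparing
#' a re-docked pose to the crystallographic conformation in a shared
#' frame.
#'
#' @param mol_a,mol_b `molecule` objects with identical atom ordering.
#' @param superimpose superimpose before measuring (default TRUE).
#' @return RMSD in Angstroms.
#' @export
pose_rmsd <- function(mol_a, mol_b, superimpose = TRUE) {
  if (nrow(mol_a) != nrow(mol_b))
    stop("atom count mismatch: ", nrow(mol_a), " vs ", nrow(mol_b),
         call. = FALSE)
  if (!all(toupper(mol_a$element) == toupper(mol_b$element)))
    stop("element sequences differ: poses are not the same molecule",
         call. = FALSE)
  xa <- coords(mol_a); xb <- coords(mol_b)
  if (superimpose) {
    bio3d::rmsd(as.vector(t(xa)), as.vector(t(xb)), fit = TRUE)
  } else {
    sqrt(mean(rowSums((xa - xb)^2)))
  }
}

# heavy = not hydrogen
heavy_atoms <- function(mol) {
  as.data.frame(mol)[toupper(mol$element) != "H", , drop = FALSE]
}

residue_label <- function(resid, resno) {
  nice <- paste0(substr(resid, 1, 1), tolower(substr(resid, 2, nchar(resid))))
  paste0(nice, resno)
}

#' Residues in contact with a ligand
#'
#' A residue is a contact when any of its heavy atoms lies within
#' `cutoff` of any ligand heavy atom.
#'
#' @param protein `molecule` with residue labels.
#' @param ligand `molecule`.
#' @param cutoff heavy-atom distance cutoff in Angstroms (default 4.5).
#' @return data.frame with `residue` and `min_dist`, sorted by distance.
#' @export
contact_residues <- function(protein, ligand, cutoff = 4.5) {
  if (all(is.na(protein$resid)))
    stop("protein has no residue labels", call. = FALSE)
  prot <- heavy_atoms(protein)
  lig <- heavy_atoms(ligand)
  pm <- as.matrix(prot[c("x", "y", "z")])
  lm_ <- as.matrix(lig[c("x", "y", "z")])
  # protein-atom x ligand-atom distance matrix
  d2 <- outer(rowSums(pm^2), rep(1, nrow(lm_))) +
    outer(rep(1, nrow(pm)), rowSums(lm_^2)) - 2 * pm %*% t(lm_)
  dmin <- sqrt(pmax(apply(d2, 1L, min), 0))
  lab <- residue_label(prot$resid, prot$resno)
  res_min <- tapply(dmin, lab, min)
  res_min <- res_min[res_min <= cutoff]
  out <- data.frame(residue = names(res_min), min_dist = as.numeric(res_min),
                    stringsAsFactors = FALSE)
  out[order(out$min_dist), , drop = FALSE]
}

# Polar hydrogens of one molecule together with their donor heavy atom.
.donor_pairs <- function(mol, hcov = 1.3) {
  m <- as.data.frame(mol)
  hs <- which(toupper(m$element) == "H")
  don <- which(toupper(m$element) %in% c("N", "O"))
  if (length(hs) == 0L || length(don) == 0L)
    return(data.frame(h = integer(), d = integer()))
  hm <- as.matrix(m[hs, c("x", "y", "z")])
  dm <- as.matrix(m[don, c("x", "y", "z")])
  d2 <- outer(rowSums(hm^2), rep(1, nrow(dm))) +
    outer(rep(1, nrow(hm)), rowSums(dm^2)) - 2 * hm %*% t(dm)
  hit <- which(sqrt(pmax(d2, 0)) <= hcov, arr.ind = TRUE)
  data.frame(h = hs[hit[, 1L]], d = don[hit[, 2L]])
}

#' Geometric hydrogen-bond detection between two molecules
#'
#' Donors are N/O atoms carrying a hydrogen (a hydrogen within 1.3 A of
#' the heavy atom, or flagged polar in PDBQT input); acceptors are N/O
#' atoms of the partner molecule. A bond is reported when the
#' donor-acceptor distance is at most `max_da_dist` and the D-H...A
#' angle is at least `min_dha_angle`. Both donor directions are tried.
#'
#' @param protein,ligand `molecule` objects.
#' @param max_da_dist donor-acceptor distance cutoff, Angstroms (3.5).
#' @param min_dha_angle minimal D-H...A angle, degrees (120).
#' @return data.frame with `donor`, `acceptor`, `distance`, `angle`,
#'   `direction`; zero rows when no bond qualifies.
#' @export
hydrogen_bonds <- function(protein, ligand, max_da_dist = 3.5,
                           min_dha_angle = 120) {
  one_way <- function(dmol, amol, direction) {
    dp <- .donor_pairs(dmol)
    acc <- which(toupper(amol$element) %in% c("N", "O"))
    if (nrow(dp) == 0L || length(acc) == 0L) return(NULL)
    dxyz <- coords(dmol); axyz <- coords(amol)
    rows <- list()
    for (i in seq_len(nrow(dp))) {
      D <- dxyz[dp$d[i], ]; H <- dxyz[dp$h[i], ]
      for (a in acc) {
        A <- axyz[a, ]
        dda <- sqrt(sum((D - A)^2))
        if (dda > max_da_dist) next
        v1 <- D - H; v2 <- A - H
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        if (ang < min_dha_angle) next
        dlab <- if (!is.na(dmol$resid[dp$d[i]]))
          residue_label(dmol$resid[dp$d[i]], dmol$resno[dp$d[i]])
        else paste0(dmol$element[dp$d[i]], dp$d[i])
        alab <- if (!is.na(amol$resid[a]))
          residue_label(amol$resid[a], amol$resno[a])
        else paste0(amol$element[a], a)
        rows[[length(rows) + 1L]] <- data.frame(
          donor = dlab, acceptor = alab, distance = dda, angle = ang,
          direction = direction, stringsAsFactors = FALSE)
      }
    }
    if (length(rows) > 0L) do.call(rbind, rows) else NULL
  }
  out <- rbind(one_way(protein, ligand, "protein->ligand"),
               one_way(ligand, protein, "ligand->protein"))
  if (is.null(out))
    out <- data.frame(donor = character(), acceptor = character(),
                      distance = numeric(), angle = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
  out
}
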