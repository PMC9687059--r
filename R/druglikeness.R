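# Local druglikeness evaluation: formula weights, Lipinski H-bond
# donor/acceptor counts, Moriguchi MLOGP (13-descriptor regression),
# Eisenlohr molar refractivity, and the rule-of-five verdict.

#' Parse a molecular formula string
#'
#' @param formula e.g. "C15H24O".
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) return(formula)
  s <- gsub("[[:space:]]", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1L]]
  toks <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1L]]
  if (sum(nchar(toks)) != nchar(s))
    stop("cannot parse formula: ", formula, call. = FALSE)
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(sub("^[A-Za-z]+", "", paste0(toks, "")))
  n[is.na(n)] <- 1L
  counts <- tapply(n, el, sum)
  stats::setNames(as.integer(counts), names(counts))
}

#' Molecular weight from a formula
#'
#' Standard atomic weights pinned to the 2005 IUPAC values (C 12.0107,
#' H 1.00794, O 15.9994, ...) so that printed two-decimal weights of
#' common natural products are reproduced exactly.
#'
#' @param x formula string, named element-count vector, or `compound`.
#' @return weight in g/mol.
#' @examples
#' molecular_weight("C15H24")   # 204.35
#' @export
molecular_weight <- function(x) {
  counts <- compound_formula(x)
  unknown <- setdiff(names(counts), names(ATOMIC_WEIGHTS))
  if (length(unknown) > 0L)
    stop("no atomic weight for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  sum(ATOMIC_WEIGHTS[names(counts)] * counts)
}

compound_formula <- function(x) {
  if (inherits(x, "compound")) return(x$formula)
  parse_formula(x)
}

#' Read compound structures from an SDF file
#'
#' Minimal V2000 support via ChemmineR; explicit hydrogens are used
#' when present, otherwise hydrogen counts on heteroatoms are inferred
#' from standard valences.
#'
#' @param path SDF file (may hold several molecules).
#' @return list of `compound` objects (name, atoms, bonds, formula).
#' @export
read_compounds <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
  out <- lapply(seq_along(sdf), function(i) {
    one <- sdf[[i]]
    ab <- ChemmineR::atomblock(one)
    bb <- ChemmineR::bondblock(one)
    el <- sub("_[0-9]+$", "", rownames(ab))
    atoms <- data.frame(element = el, x = ab[, 1L], y = ab[, 2L],
                        z = if (ncol(ab) >= 3L) ab[, 3L] else 0,
                        stringsAsFactors = FALSE)
    bonds <- data.frame(a1 = as.integer(bb[, 1L]), a2 = as.integer(bb[, 2L]),
                        order = as.integer(bb[, 3L]))
    counts <- table(el)
    new_compound(name = ChemmineR::sdfid(sdf)[i], atoms = atoms,
                 bonds = bonds,
                 formula = stats::setNames(as.integer(counts), names(counts)))
  })
  names(out) <- vapply(out, function(x) x$name, "")
  out
}

#' Build a compound record
#'
#' @param name compound name.
#' @param atoms optional data.frame with `element` (and coordinates).
#' @param bonds optional data.frame with `a1`, `a2`, `order`.
#' @param formula named element counts or formula string; derived from
#'   atoms when omitted.
#' @return object of class `compound`.
#' @export
new_compound <- function(name, atoms = NULL, bonds = NULL, formula = NULL) {
  if (is.null(formula)) {
    if (is.null(atoms)) stop("need a formula or an atom list", call. = FALSE)
    counts <- table(atoms$element)
    formula <- stats::setNames(as.integer(counts), names(counts))
  } else {
    formula <- compound_formula(formula)
  }
  structure(list(name = name, atoms = atoms, bonds = bonds,
                 formula = formula), class = "compound")
}

#' @export
print.compound <- function(x, ...) {
  f <- paste0(names(x$formula), ifelse(x$formula > 1, x$formula, ""),
              collapse = "")
  cat("Compound", x$name, "-", f,
      if (!is.null(x$atoms)) "(with structure)" else "(formula only)", "\n")
  invisible(x)
}

# Hydrogen counts attached to each heavy atom: explicit H neighbours,
# or inferred from standard valence when the structure carries none.
attached_h <- function(compound) {
  at <- compound$atoms; bd <- compound$bonds
  heavy <- which(at$element != "H")
  hcount <- integer(length(heavy))
  names(hcount) <- heavy
  has_explicit_h <- any(at$element == "H")
  for (k in seq_along(heavy)) {
    i <- heavy[k]
    nb <- c(bd$a2[bd$a1 == i], bd$a1[bd$a2 == i])
    if (has_explicit_h) {
      hcount[k] <- sum(at$element[nb] == "H")
    } else {
      val <- c(C = 4, N = 3, O = 2, S = 2, P = 3)[at$element[i]]
      used <- sum(bd$order[bd$a1 == i | bd$a2 == i])
      hcount[k] <- max(0L, as.integer(val - used))
    }
  }
  hcount
}

#' Count Lipinski hydrogen-bond acceptors
#'
#' The Lipinski convention: the number of nitrogen plus oxygen atoms.
#'
#' @param x `compound`, formula string, or named counts.
#' @return integer count.
#' @export
count_hb_acceptors <- function(x) {
  counts <- compound_formula(x)
  sum(counts[names(counts) %in% c("N", "O")])
}

#' Count Lipinski hydrogen-bond donors
#'
#' The number of N or O atoms carrying at least one hydrogen (each
#' heteroatom counted once). Requires a structure whenever the formula
#' contains N or O, since connectivity decides where hydrogens sit.
#'
#' @param x a `compound`.
#' @return integer count.
#' @export
count_hb_donors <- function(x) {
  if (!inherits(x, "compound")) x <- new_compound("?", formula = x)
  if (count_hb_acceptors(x) == 0L) return(0L)
  if (is.null(x$atoms) || is.null(x$bonds))
    stop("donor counting needs a structure: formula-only input has N/O",
         call. = FALSE)
  h <- attached_h(x)
  heavy_el <- x$atoms$element[as.integer(names(h))]
  sum(heavy_el %in% c("N", "O") & h >= 1L)
}

# --- Moriguchi MLOGP -------------------------------------------------

# Bond graph over heavy atoms (igraph), orders kept as edge attribute.
heavy_graph <- function(compound) {
  at <- compound$atoms; bd <- compound$bonds
  heavy <- which(at$element != "H")
  idx <- match(seq_len(nrow(at)), heavy)    # old -> new index or NA
  keep <- bd$a1 %in% heavy & bd$a2 %in% heavy
  edges <- cbind(idx[bd$a1[keep]], idx[bd$a2[keep]])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(heavy) - igraph::vcount(g)))
  igraph::E(g)$order <- bd$order[keep]
  igraph::V(g)$element <- at$element[heavy]
  g
}

# Edges that lie on some cycle (non-bridges).
ring_edges <- function(g) {
  which(!seq_len(igraph::ecount(g)) %in% igraph::bridges(g))
}

# Six-membered all-carbon rings with alternating single/double (or all
# aromatic-typed) bonds: the benzene-type rings excluded from RNG.
aromatic_rings <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::V(g)$element
  adj <- igraph::as_adj_list(g)
  found <- list()
  seen <- character()
  dfs <- function(path) {
    last <- path[length(path)]
    for (nb in as.integer(adj[[last]])) {
      if (length(path) == 6L && nb == path[1L]) {
        key <- paste(sort(path), collapse = "-")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          found[[length(found) + 1L]] <<- path
        }
      } else if (length(path) < 6L && !nb %in% path && nb > path[1L]) {
        dfs(c(path, nb))
      }
    }
  }
  for (v in seq_len(n)) if (el[v] == "C") dfs(v)
  is_arom <- function(cyc) {
    if (any(el[cyc] != "C")) return(FALSE)
    ords <- vapply(seq_along(cyc), function(i) {
      a <- cyc[i]; b <- cyc[if (i == length(cyc)) 1L else i + 1L]
      igraph::E(g)$order[igraph::get_edge_ids(g, c(a, b))]
    }, 0)
    all(ords == 4) || (sum(ords == 2) == 3L && sum(ords == 1) == 3L &&
                         all(abs(diff(ords)) == 1))
  }
  found[vapply(found, is_arom, TRUE)]
}

#' Moriguchi MLOGP topological descriptors
#'
#' The thirteen descriptors of the Moriguchi octanol-water partition
#' regression, computed from the heavy-atom bond graph: CX (weighted
#' carbon/halogen count), NO (N+O count), PRX (N/O proximity), UB
#' (unsaturated bonds), HB (intramolecular H-bond dummy), POL (aromatic
#' polar substituents), AMP (amphoteric), ALK (hydrocarbon with at most
#' one double bond), RNG (non-aromatic ring dummy), QN (quaternary N),
#' NO2 (nitro groups), NCS (isothiocyanate), BLM (beta-lactam).
#'
#' @param compound a `compound` with atoms and bonds.
#' @return named numeric vector of the 13 descriptors.
#' @export
mlogp_descriptors <- function(compound) {
  if (is.null(compound$atoms) || is.null(compound$bonds))
    stop("MLOGP needs a structure (atom/bond graph)", call. = FALSE)
  el_all <- compound$atoms$element
  covered <- c("C", "H", "N", "O", "S", "P", "F", "Cl", "Br", "I")
  if (!all(el_all %in% covered))
    stop("element outside MLOGP coverage: ",
         paste(setdiff(el_all, covered), collapse = ", "), call. = FALSE)
  g <- heavy_graph(compound)
  el <- igraph::V(g)$element
  ord <- igraph::E(g)$order
  cx_w <- c(C = 1, F = 0.5, Cl = 1, Br = 1.5, I = 2)
  CX <- sum(cx_w[el], na.rm = TRUE)
  NO <- sum(el %in% c("N", "O"))

  topo <- igraph::distances(g)
  het <- which(el %in% c("N", "O"))
  PRX <- 0
  if (length(het) >= 2L) {
    for (i in seq_along(het)[-length(het)]) for (j in (i + 1L):length(het)) {
      d <- topo[het[i], het[j]]
      if (d == 1) PRX <- PRX + 2 else if (d == 2) PRX <- PRX + 1
    }
  }

  UB <- sum(ord == 2L) + sum(ord == 3L) + 0.5 * sum(ord == 4L)

  # attached_h() enumerates heavy atoms in the same order as the heavy
  # graph's vertices, so h[v] is the H count of heavy-graph vertex v.
  h <- attached_h(compound)
  donors <- which(el %in% c("N", "O") & h >= 1L)
  HB <- 0
  if (length(donors) > 0L && length(het) > 1L) {
    for (d in donors) for (a in setdiff(het, d)) {
      if (topo[d, a] %in% c(3, 4)) { HB <- 1; break }
    }
  }

  arom <- aromatic_rings(g)
  arom_atoms <- unique(unlist(arom))
  POL <- 0
  if (length(arom_atoms) > 0L && length(het) > 0L) {
    for (a in het) {
      nb <- as.integer(igraph::neighbors(g, a))
      if (any(nb %in% arom_atoms) && !a %in% arom_atoms) POL <- POL + 1
    }
  }

  deg_heavy <- igraph::degree(g)
  nh <- h  # hydrogens per heavy atom, heavy order
  QN <- 0; NO2 <- 0; NCS <- 0
  for (v in which(el == "N")) {
    tot_deg <- deg_heavy[v] + nh[v]
    nbs <- as.integer(igraph::neighbors(g, v))
    term_o <- nbs[el[nbs] == "O" & deg_heavy[nbs] == 1L]
    if (length(term_o) >= 2L) NO2 <- NO2 + 1
    else if (tot_deg >= 4L) {
      QN <- QN + if (length(term_o) == 1L) 0.5 else 1
    }
  }
  # isothiocyanate N=C=S / thiocyanate S-C#N
  for (v in which(el == "C")) {
    eids <- igraph::incident(g, v)
    nbs <- as.integer(igraph::neighbors(g, v))
    o <- igraph::E(g)$order[eids]
    if (any(el[nbs] == "N" & o == 2) && any(el[nbs] == "S" & o == 2))
      NCS <- NCS + 1
    if (any(el[nbs] == "N" & o == 3) && any(el[nbs] == "S" & o == 1))
      NCS <- NCS + 0.5
  }

  hydrocarbon <- all(el_all %in% c("C", "H"))
  ALK <- as.numeric(hydrocarbon && length(arom) == 0L &&
                      sum(ord == 2L) <= 1L && sum(ord >= 3L) == 0L)

  re <- ring_edges(g)
  arom_edges <- unlist(lapply(arom, function(cyc) {
    vapply(seq_along(cyc), function(i) {
      igraph::get_edge_ids(g, c(cyc[i], cyc[if (i == length(cyc)) 1L else i + 1L]))
    }, 0)
  }))
  RNG <- as.numeric(length(setdiff(re, arom_edges)) > 0L)

  BLM <- 0
  # beta-lactam: 4-ring with N and a ring carbon double-bonded to O
  if (any(el == "N")) {
    for (v in which(el == "N")) {
      nbs <- as.integer(igraph::neighbors(g, v))
      for (c1 in nbs[el[nbs] == "C"]) {
        c1nb <- as.integer(igraph::neighbors(g, c1))
        o2 <- igraph::E(g)$order[igraph::incident(g, c1)]
        has_co <- any(el[c1nb] == "O" & o2[match(c1nb, c1nb)] == 2)
        if (!has_co) next
        # ring closure v-c1-x-y-v of size 4
        for (x in setdiff(c1nb, v)) {
          xnb <- as.integer(igraph::neighbors(g, x))
          if (any(xnb %in% setdiff(nbs, c1))) BLM <- 1
        }
      }
    }
  }

  c(CX = CX, NO = NO, PRX = PRX, UB = UB, HB = HB, POL = POL, AMP = 0,
    ALK = ALK, RNG = RNG, QN = QN, NO2 = NO2, NCS = NCS, BLM = BLM)
}

#' Moriguchi MLOGP
#'
#' Evaluates the published 13-descriptor Moriguchi regression for the
#' octanol-water partition coefficient on a structure's topological
#' descriptors (see [mlogp_descriptors()]).
#'
#' @param compound a `compound` with atoms and bonds.
#' @return MLOGP value (unitless).
#' @examples
#' sdf <- system.file("extdata", "sdf", "caryophyllene.sdf",
#'                    package = "phytodock")
#' mlogp(read_compounds(sdf)[[1]])
#' @export
mlogp <- function(compound) {
  d <- mlogp_descriptors(compound)
  1.244 * d[["CX"]]^0.6 - 1.017 * d[["NO"]]^0.9 + 0.406 * d[["PRX"]] -
    0.145 * d[["UB"]]^0.8 + 0.511 * d[["HB"]] + 0.268 * d[["POL"]] -
    2.215 * d[["AMP"]] + 0.912 * d[["ALK"]] - 0.392 * d[["RNG"]] -
    3.684 * d[["QN"]] + 0.474 * d[["NO2"]] + 1.582 * d[["NCS"]] +
    0.773 * d[["BLM"]] - 1.041
}

#' Molar refractivity (Eisenlohr atomic contributions)
#'
#' Classic atomic-refraction sum: C 2.418, H 1.100, O by environment
#' (hydroxyl 1.525, ether 1.643, carbonyl 2.211), N 2.322, plus 1.733
#' per double bond and 2.398 per triple bond. Reported for information;
#' it does not enter the rule-of-five verdict.
#'
#' @param compound a `compound` with atoms and bonds.
#' @return molar refractivity, cm^3/mol.
#' @export
molar_refractivity <- function(compound) {
  if (is.null(compound$atoms) || is.null(compound$bonds))
    stop("molar refractivity needs a structure", call. = FALSE)
  g <- heavy_graph(compound)
  el <- igraph::V(g)$element
  ord <- igraph::E(g)$order
  h <- attached_h(compound)
  nH <- sum(compound$formula["H"], na.rm = TRUE)
  if (!any(compound$atoms$element == "H")) nH <- sum(h)
  mr <- sum(el == "C") * 2.418 + nH * 1.100 + sum(el == "N") * 2.322 +
    sum(el == "S") * 7.69
  for (v in which(el == "O")) {
    eids <- igraph::incident(g, v)
    if (any(igraph::E(g)$order[eids] == 2)) mr <- mr + 2.211
    else if (h[v] >= 1L) mr <- mr + 1.525
    else mr <- mr + 1.643
  }
  mr + (sum(ord == 2L) + 0.5 * sum(ord == 4L)) * 1.733 +
    sum(ord == 3L) * 2.398
}

#' Lipinski rule-of-five assessment
#'
#' Violations from {MW > 500, MLOGP > 4.15, HBA > 10, HBD > 5}; a
#' compound is druglike when it has at most one violation. The
#' lipophilicity criterion is the MLOGP > 4.15 form of the rule.
#'
#' @param mw molecular weight, g/mol.
#' @param mlogp Moriguchi logP.
#' @param hba hydrogen-bond acceptor count.
#' @param hbd hydrogen-bond donor count.
#' @return list with `violations` (character vector), `druglike`
#'   (logical) and `verdict` (printed-style string, e.g.
#'   "Yes; 1 violation: MLOGP > 4.15").
#' @export
lipinski_assess <- function(mw, mlogp, hba, hbd) {
  v <- character()
  if (mw > 500) v <- c(v, "MW > 500")
  if (mlogp > 4.15) v <- c(v, "MLOGP > 4.15")
  if (hba > 10) v <- c(v, "HBA > 10")
  if (hbd > 5) v <- c(v, "HBD > 5")
  druglike <- length(v) <= 1L
  verdict <- paste0(if (druglike) "Yes" else "No", "; ", length(v),
                    " violation", if (length(v) > 1L) "s" else "",
                    if (length(v) > 0L) paste0(": ", paste(v, collapse = ", ")))
  list(violations = v, druglike = druglike, verdict = verdict)
}

#' Druglikeness table for a set of compounds
#'
#' Computes molecular weight, MLOGP, H-bond acceptor and donor counts,
#' molar refractivity and the rule-of-five verdict for each compound.
#'
#' @param compounds list of `compound` objects (see [read_compounds()]).
#' @return data.frame, one row per compound, with columns `name`, `mw`,
#'   `mlogp`, `hba`, `hbd`, `molar_refractivity`, `druglike`, `verdict`.
#' @examples
#' dir <- system.file("extdata", "sdf", package = "phytodock")
#' cmp <- unlist(lapply(list.files(dir, full.names = TRUE), read_compounds),
#'               recursive = FALSE)
#' adme_table(cmp)[c("name", "mlogp", "verdict")]
#' @export
adme_table <- function(compounds) {
  rows <- lapply(compounds, function(cmp) {
    mw <- molecular_weight(cmp)
    ml <- mlogp(cmp)
    hba <- count_hb_acceptors(cmp)
    hbd <- count_hb_donors(cmp)
    mr <- molar_refractivity(cmp)
    lp <- lipinski_assess(mw, ml, hba, hbd)
    data.frame(name = cmp$name, mw = mw, mlogp = ml, hba = hba, hbd = hbd,
               molar_refractivity = mr, druglike = lp$druglike,
               verdict = lp$verdict, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
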