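# Seeded synthetic-data generators. Each generator emulates the
# statistical or geometric structure one pipeline stage assumes and
# returns a machine-readable truth record next to the data, so every
# stage is testable without downloads. All randomness goes through R's
# default RNG under the supplied seed; outputs are bit-reproducible.

#' Simulate a logarithmic dose-response table
#'
#' response = a*ln(concentration) + b + N(0, noise_sd).
#'
#' @param a,b true slope (% per ln(ug/mL)) and intercept (%).
#' @param noise_sd Gaussian noise SD in percent (default 2, a typical
#'   replicate SEM scale for plate-reader inhibition data).
#' @param concentrations dose levels, ug/mL (defaults to the 2-fold
#'   series 3.1 ... 100 used in the packaged assay fixture).
#' @param seed RNG seed.
#' @return list with `data` (concentration/response data.frame) and
#'   `truth` (a, b, noise_sd, analytic ic50 = exp((50-b)/a), seed).
#' @export
sim_dose_response <- function(a = 11.08, b = 12.68, noise_sd = 2,
                              concentrations = c(3.1, 6.3, 12.5, 25, 50, 100),
                              seed = 1) {
  stopifnot(all(concentrations > 0), noise_sd >= 0)
  set.seed(seed)
  y <- a * log(concentrations) + b + stats::rnorm(length(concentrations),
                                                  0, noise_sd)
  list(data = data.frame(concentration = concentrations, response = y),
       truth = list(a = a, b = b, noise_sd = noise_sd,
                    ic50 = exp((50 - b) / a), seed = seed))
}

#' Simulate a toy protein-ligand complex
#'
#' A random atom cluster stands in for the binding-site side of a
#' protein and a second, smaller cluster for the ligand, their
#' centroids separated along x by `separation`. With one atom per
#' molecule the complex realises the closed-form CF1 = const -
#' zeta*SUMRLRE configuration used to validate the complementarity
#' regression.
#'
#' @param n_protein,n_ligand atom counts (>= 1).
#' @param separation centroid separation, Angstroms (> 0).
#' @param elements element pool for random draws.
#' @param spread cluster SD, Angstroms.
#' @param seed RNG seed.
#' @param dir optional directory: writes `protein.pdb` and `ligand.xyz`.
#' @return list with `protein` and `ligand` (`molecule` objects),
#'   `truth` (separation, counts, seed) and, when `dir` is given,
#'   `files`.
#' @export
sim_toy_complex <- function(n_protein = 50, n_ligand = 10, separation = 3,
                            elements = c("C", "C", "C", "N", "O", "H"),
                            spread = 1.5, seed = 1, dir = NULL) {
  stopifnot(separation > 0, n_protein >= 1, n_ligand >= 1)
  set.seed(seed)
  cluster <- function(n, center) {
    data.frame(element = sample(elements, n, replace = TRUE),
               x = stats::rnorm(n, center[1L], spread),
               y = stats::rnorm(n, center[2L], spread),
               z = stats::rnorm(n, center[3L], spread),
               stringsAsFactors = FALSE)
  }
  pa <- cluster(n_protein, c(-separation / 2, 0, 0))
  # label the pseudo-protein with sequential alanine residues so that
  # contact detection has residue labels to report
  pa$name <- pa$element
  pa$resid <- "ALA"
  pa$resno <- seq_len(n_protein)
  pa$chain <- "A"
  la <- cluster(n_ligand, c(separation / 2, 0, 0))
  protein <- new_molecule(pa, label = "toy-protein")
  ligand <- new_molecule(la, label = "toy-ligand")
  out <- list(protein = protein, ligand = ligand,
              truth = list(separation = separation, n_protein = n_protein,
                           n_ligand = n_ligand, seed = seed))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pf <- file.path(dir, "protein.pdb")
    lf <- file.path(dir, "ligand.xyz")
    write_pdb(protein, pf)
    write_xyz(ligand, lf, comment = paste("seed", seed))
    out$files <- c(protein = pf, ligand = lf)
  }
  out
}

#' Simulate a docking affinity table
#'
#' Uniform affinities over `range`; the truth records how many fall at
#' or below the -8 kcal/mol hit threshold.
#'
#' @param n number of ligands (>= 0).
#' @param range affinity range, kcal/mol.
#' @param threshold hit threshold recorded in the truth (default -8).
#' @param seed RNG seed.
#' @return list with `data` (ligand/affinity data.frame) and `truth`.
#' @export
sim_affinity_table <- function(n = 17, range = c(-10, -5), threshold = -8,
                               seed = 1) {
  stopifnot(n >= 0)
  set.seed(seed)
  aff <- if (n > 0) round(stats::runif(n, range[1L], range[2L]), 1) else numeric()
  data <- data.frame(ligand = if (n > 0) sprintf("ligand_%02d", seq_len(n))
                              else character(),
                     affinity = aff, stringsAsFactors = FALSE)
  list(data = data,
       truth = list(n_hits = sum(aff <= threshold), threshold = threshold,
                    seed = seed))
}

#' Simulate a GC-MS peak table
#'
#' Log-normal raw areas (heavy-tailed, as chromatogram integrals are)
#' over increasing retention times; truth percentages are computed
#' analytically from the drawn areas.
#'
#' @param n number of peaks (>= 1; default 17, a typical essential-oil
#'   constituent count).
#' @param meanlog,sdlog log-normal area parameters.
#' @param seed RNG seed.
#' @return list with `data` (peak/rt_min/compound/area) and `truth`
#'   (area percentages).
#' @export
sim_peak_table <- function(n = 17, meanlog = 11, sdlog = 1.5, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  area <- stats::rlnorm(n, meanlog, sdlog)
  data <- data.frame(peak = seq_len(n),
                     rt_min = round(sort(stats::runif(n, 10, 50)), 1),
                     compound = sprintf("compound_%02d", seq_len(n)),
                     area = area, stringsAsFactors = FALSE)
  list(data = data,
       truth = list(area_pct = 100 * area / sum(area), seed = seed))
}
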