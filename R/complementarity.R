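# Electronic-complementarity scoring of enzyme-ligand complexes.
#
# Each molecule's outer-shell electron density is modelled as a sum of
# single-exponential atomic terms rho_a(r) = rho_cnt_a * exp(-zeta_a*r).
# At a point m in the intermolecular space the complementarity factor
#
#   CF1 = ln(rho_E * rho_cnt_e / N_e) + ln(rho_L * rho_cnt_l / N_l)
#
# combines the enzyme and ligand densities at m, each normalised by the
# center density and atomic number of the atom contributing most at m.
# SUMRLRE = R_me + R_ml is the summed distance from m to those two
# atoms. Over a shell of sampled points, CF1 regresses linearly on
# SUMRLRE; a tight, appropriately-placed regression indicates an
# electronically complementary complex.

#' Default atomic density parameters
#'
#' Per-element single-exponential outer-shell parameters: `rho_cnt`,
#' the electron density at the atom center (e/A^3, Slater 1s density at
#' the nucleus); `zeta`, the outer-shell decay constant (1/A, twice the
#' Slater valence exponent per Bohr radius); and the atomic number.
#' These are declared, overridable model constants, not a fit to any
#' reference quantum-chemical density; report results together with the
#' parameter table used.
#'
#' @return data.frame with columns `element`, `rho_cnt`, `zeta`,
#'   `atomic_number`, row names the element symbols.
#' @export
default_density_params <- function() {
  read_density_params(system.file("extdata", "density_params.tsv",
                                  package = "phytodock"))
}

#' Read an atomic density parameter table
#'
#' @param path TSV with columns `element,rho_cnt,zeta,atomic_number`.
#' @return data.frame keyed by element (row names).
#' @export
read_density_params <- function(path) {
  df <- read_table_auto(path)
  need <- c("element", "rho_cnt", "zeta", "atomic_number")
  if (!all(need %in% names(df)))
    stop("density parameter table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(df$rho_cnt <= 0) || any(df$zeta <= 0) || any(df$atomic_number < 1))
    stop("density parameters out of range (rho_cnt,zeta > 0; Z >= 1)",
         call. = FALSE)
  rownames(df) <- df$element
  df
}

params_for <- function(mol, params) {
  el <- canonical_element(mol$element)
  miss <- setdiff(unique(el), rownames(params))
  if (length(miss) > 0L)
    stop("no density parameters for element(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  params[el, , drop = FALSE]
}

#' Molecular electron density at points
#'
#' Sums the exponential atomic terms of `mol` at each query point and
#' identifies the atom with the greatest single contribution (ties
#' broken by lowest atom index).
#'
#' @param mol a `molecule`.
#' @param params density parameter table covering every element of
#'   `mol` (see [default_density_params()]).
#' @param points numeric n x 3 matrix (or length-3 vector) of
#'   Cartesian points, Angstroms.
#' @return data.frame with `rho` (e/A^3), `atom` (argmax index),
#'   `dist` (distance from the point to that atom, A).
#' @export
molecular_density <- function(mol, params, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  p <- params_for(mol, params)
  xyz <- coords(mol)
  n <- nrow(points)
  rho <- numeric(n); atom <- integer(n); dist <- numeric(n)
  chunk <- max(1L, floor(2e6 / nrow(xyz)))
  for (start in seq(1L, n, by = chunk)) {
    ix <- start:min(start + chunk - 1L, n)
    pts <- points[ix, , drop = FALSE]
    d2 <- outer(rowSums(pts^2), rep(1, nrow(xyz))) +
      outer(rep(1, nrow(pts)), rowSums(xyz^2)) - 2 * pts %*% t(xyz)
    d <- sqrt(pmax(d2, 0))
    terms <- sweep(exp(sweep(d, 2L, -p$zeta, `*`)), 2L, p$rho_cnt, `*`)
    rho[ix] <- rowSums(terms)
    am <- max.col(terms, ties.method = "first")
    atom[ix] <- am
    dist[ix] <- d[cbind(seq_len(nrow(d)), am)]
  }
  data.frame(rho = rho, atom = atom, dist = dist)
}

#' Complementarity factor at a point
#'
#' CF1 = ln(rho_e * rho_cnt_e / N_e) + ln(rho_l * rho_cnt_l / N_l); the
#' two sides enter symmetrically.
#'
#' @param rho_e,rho_l molecular densities at the point (e/A^3, > 0).
#' @param e_entry,l_entry single-row parameter entries (with `rho_cnt`
#'   and `atomic_number`) of the maximal-contribution enzyme and ligand
#'   atoms.
#' @return unitless CF1 value (vectorized).
#' @export
cf1_point <- function(rho_e, rho_l, e_entry, l_entry) {
  if (any(rho_e <= 0) || any(rho_l <= 0))
    stop("densities must be positive", call. = FALSE)
  log(rho_e * e_entry$rho_cnt / e_entry$atomic_number) +
    log(rho_l * l_entry$rho_cnt / l_entry$atomic_number)
}

#' Sample intermolecular grid points
#'
#' Deterministic cubic grid over the ligand bounding box padded by
#' `padding`, aligned to multiples of `spacing`. A point is kept when
#' both molecular densities fall inside `band` (the low-density
#' intermolecular shell) and the point is at least `min_dist` from
#' every atom of either molecule.
#'
#' @param protein,ligand `molecule` objects.
#' @param params density parameter table.
#' @param spacing grid spacing, Angstroms (default 0.3).
#' @param padding bounding-box padding, Angstroms (default 4).
#' @param band length-2 density window, e/A^3 (default c(1e-4, 1e-1)).
#' @param min_dist clash floor, Angstroms (default 1).
#' @return list with `points` (n x 3 matrix), `rho_e`, `rho_l`,
#'   `e_atom`, `l_atom`, `r_me`, `r_ml`. Zero kept points triggers a
#'   warning, not an error.
#' @export
sample_complementarity_points <- function(protein, ligand, params,
                                          spacing = 0.3, padding = 4,
                                          band = c(1e-4, 1e-1),
                                          min_dist = 1) {
  stopifnot(spacing > 0, band[1L] < band[2L])
  lxyz <- coords(ligand)
  ax <- function(k) {
    lo <- floor((min(lxyz[, k]) - padding) / spacing) * spacing
    hi <- ceiling((max(lxyz[, k]) + padding) / spacing) * spacing
    seq(lo, hi, by = spacing)
  }
  grid <- as.matrix(expand.grid(x = ax(1), y = ax(2), z = ax(3),
                                KEEP.OUT.ATTRS = FALSE))
  de <- molecular_density(protein, params, grid)
  dl <- molecular_density(ligand, params, grid)
  pxyz <- coords(protein)
  near <- function(pts, xyz) {
    d2 <- outer(rowSums(pts^2), rep(1, nrow(xyz))) +
      outer(rep(1, nrow(pts)), rowSums(xyz^2)) - 2 * pts %*% t(xyz)
    sqrt(pmax(apply(d2, 1L, min), 0))
  }
  keep <- de$rho >= band[1L] & de$rho <= band[2L] &
    dl$rho >= band[1L] & dl$rho <= band[2L]
  if (any(keep)) {
    kept <- which(keep)
    dmin <- pmin(near(grid[kept, , drop = FALSE], pxyz),
                 near(grid[kept, , drop = FALSE], lxyz))
    keep[kept[dmin < min_dist]] <- FALSE
  }
  if (!any(keep)) warning("no grid points survive the density band")
  list(points = grid[keep, , drop = FALSE],
       rho_e = de$rho[keep], rho_l = dl$rho[keep],
       e_atom = de$atom[keep], l_atom = dl$atom[keep],
       r_me = de$dist[keep], r_ml = dl$dist[keep])
}

#' Fit the CF1-versus-SUMRLRE regression
#'
#' Ordinary least squares CF1 = a_cf1 + b_cf1 * SUMRLRE. `sigma` is the
#' residual standard deviation sqrt(SSR/(n-2)); `rcor2` the squared
#' Pearson correlation.
#'
#' @param sumrlre summed distances R_me + R_ml, Angstroms.
#' @param cf1 complementarity factor values.
#' @param points optional per-point record data.frame carried along.
#' @return object of class `cf1_fit` with `a_cf1`, `b_cf1`, `rcor2`,
#'   `sigma`, `n_points`, `min_sumrlre`, `max_cf1`, `model`, `points`.
#' @export
cf1_fit <- function(sumrlre, cf1, points = NULL) {
  n <- length(sumrlre)
  if (n < 3L) stop("insufficient sampling: need at least 3 points",
                   call. = FALSE)
  model <- stats::lm(cf1 ~ sumrlre)
  ssr <- sum(residuals(model)^2)
  structure(list(
    a_cf1 = unname(coef(model)[1L]), b_cf1 = unname(coef(model)[2L]),
    rcor2 = suppressWarnings(summary(model)$r.squared),
    sigma = sqrt(ssr / (n - 2L)),
    n_points = n, min_sumrlre = min(sumrlre), max_cf1 = max(cf1),
    model = model, points = points), class = "cf1_fit")
}

#' Electronic-complementarity profile of a complex
#'
#' Samples the intermolecular shell, evaluates SUMRLRE and CF1 at every
#' point, and fits the CF1-versus-SUMRLRE regression.
#'
#' @inheritParams sample_complementarity_points
#' @return a [cf1_fit()] object; `$points` holds the per-point table
#'   (x, y, z, rho_e, rho_l, e_atom, l_atom, r_me, r_ml, sumrlre, cf1).
#' @examples
#' params <- default_density_params()
#' cx <- sim_toy_complex(n_protein = 30, n_ligand = 8, separation = 3,
#'                       seed = 7)
#' fit <- complementarity_profile(cx$protein, cx$ligand, params,
#'                                spacing = 0.5)
#' fit
#' @export
complementarity_profile <- function(protein, ligand,
                                    params = default_density_params(),
                                    spacing = 0.3, padding = 4,
                                    band = c(1e-4, 1e-1), min_dist = 1) {
  s <- sample_complementarity_points(protein, ligand, params, spacing,
                                     padding, band, min_dist)
  n <- nrow(s$points)
  if (n < 3L) stop("insufficient sampling: only ", n,
                   " intermolecular points survive", call. = FALSE)
  ep <- params_for(protein, params)[s$e_atom, , drop = FALSE]
  lp <- params_for(ligand, params)[s$l_atom, , drop = FALSE]
  cf1 <- cf1_point(s$rho_e, s$rho_l, ep, lp)
  sumrlre <- s$r_me + s$r_ml
  pts <- data.frame(x = s$points[, 1L], y = s$points[, 2L],
                    z = s$points[, 3L], rho_e = s$rho_e, rho_l = s$rho_l,
                    e_atom = s$e_atom, l_atom = s$l_atom,
                    r_me = s$r_me, r_ml = s$r_ml,
                    sumrlre = sumrlre, cf1 = cf1)
  fit <- cf1_fit(sumrlre, cf1, points = pts)
  attr(fit, "config") <- list(spacing = spacing, padding = padding,
                              band = band, min_dist = min_dist)
  fit
}

#' @export
print.cf1_fit <- function(x, ...) {
  cat("CF1 ~ SUMRLRE complementarity regression\n")
  cat(sprintf("  aCF1 %.3f  bCF1 %.3f  Rcor2 %.3f  Sigma %.2f\n",
              x$a_cf1, x$b_cf1, x$rcor2, x$sigma))
  cat(sprintf("  Npoints %d  MIN(SUMRLRE) %.3f  MAX(CF1) %.3f\n",
              x$n_points, x$min_sumrlre, x$max_cf1))
  invisible(x)
}

#' @export
summary.cf1_fit <- function(object, ...) {
  out <- data.frame(aCF1 = object$a_cf1, bCF1 = object$b_cf1,
                    Rcor2 = object$rcor2, Sigma = object$sigma,
                    Npoints = object$n_points,
                    MIN_SUMRLRE = object$min_sumrlre,
                    MAX_CF1 = object$max_cf1)
  class(out) <- c("summary.cf1_fit", "data.frame")
  out
}

#' @export
coef.cf1_fit <- function(object, ...) {
  c(a_cf1 = object$a_cf1, b_cf1 = object$b_cf1)
}

#' @export
predict.cf1_fit <- function(object, newdata = NULL, ...) {
  s <- if (is.null(newdata)) object$points$sumrlre
       else if (is.data.frame(newdata)) newdata$sumrlre
       else as.numeric(newdata)
  object$a_cf1 + object$b_cf1 * s
}

#' @export
residuals.cf1_fit <- function(object, ...) {
  residuals(object$model)
}

#' @export
plot.cf1_fit <- function(x, ...) {
  if (is.null(x$points)) stop("no per-point records stored", call. = FALSE)
  graphics::plot(x$points$sumrlre, x$points$cf1, pch = ".",
                 xlab = "SUMRLRE (A)", ylab = "CF1", ...)
  graphics::abline(x$a_cf1, x$b_cf1)
  invisible(x)
}

#' Assess a complementarity result against the selection principles
#'
#' A complex passes when the regression correlation Rcor2 is at least
#' `r2_min` (default 0.81) and the maximal complementarity factor
#' MAX(CF1), which characterises overlap efficiency, falls inside
#' `cf1_range` (default [-5, -2]). When a reference complex is given
#' the absolute coefficient differences |aCF1 - a_ref| and
#' |bCF1 - b_ref| are reported for closeness, without a hard cutoff.
#'
#' @param result a `cf1_fit` (or list with `rcor2`, `max_cf1`, and
#'   optionally `a_cf1`, `b_cf1`).
#' @param reference optional reference `cf1_fit` or list.
#' @param r2_min minimal Rcor2.
#' @param cf1_range admissible MAX(CF1) window.
#' @return list with `pass`, `reasons` (character, empty when passing),
#'   and `coef_delta` when a reference is given.
#' @export
assess_complementarity <- function(result, reference = NULL,
                                   r2_min = 0.81, cf1_range = c(-5, -2)) {
  reasons <- character()
  if (result$rcor2 < r2_min)
    reasons <- c(reasons, sprintf("Rcor2 %.3f below %.2f", result$rcor2,
                                  r2_min))
  if (result$max_cf1 < cf1_range[1L] || result$max_cf1 > cf1_range[2L])
    reasons <- c(reasons,
                 sprintf("MAX(CF1) %.3f outside [%g, %g]: overlap efficiency out of range",
                         result$max_cf1, cf1_range[1L], cf1_range[2L]))
  out <- list(pass = length(reasons) == 0L, reasons = reasons)
  if (!is.null(reference)) {
    out$coef_delta <- c(a = abs(result$a_cf1 - reference$a_cf1),
                        b = abs(result$b_cf1 - reference$b_cf1))
  }
  out
}
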