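# Shared builders for the test suite. All fixtures are constructed in
# code; packaged tables come from inst/extdata.

ext <- function(...) system.file("extdata", ..., package = "phytodock")

mol <- function(elements, xyz, ...) {
  new_molecule(data.frame(element = elements, x = xyz[, 1], y = xyz[, 2],
                          z = xyz[, 3], ..., stringsAsFactors = FALSE))
}

# Uniform random rotation matrix (det +1) for rigid-transform tests.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(m, R, t) {
  x <- coords(m) %*% t(R)
  m$x <- x[, 1] + t[1]; m$y <- x[, 2] + t[2]; m$z <- x[, 3] + t[3]
  m
}

# One-element density table for closed-form checks.
unit_params <- function(element = "H", rho_cnt = 1, zeta = 2, z = 1) {
  df <- data.frame(element = element, rho_cnt = rho_cnt, zeta = zeta,
                   atomic_number = z, stringsAsFactors = FALSE)
  rownames(df) <- df$element
  df
}

write_lines_tmp <- function(lines, fileext) {
  path <- withr::local_tempfile(fileext = fileext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

load_hit_compounds <- function() {
  files <- list.files(ext("sdf"), full.names = TRUE)
  unlist(lapply(files, read_compounds), recursive = FALSE)
}
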