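# Bioassay statistics: DPPH percent inhibition, MTT percent viability,
# replicate aggregation, and the logarithmic dose-response fit
# y = a*ln(x) + b with its IC50.

#' DPPH percent inhibition from absorbances
#'
#' 100 * (A_control - A_sample) / A_control. Negative values are
#' possible when the sample absorbs more than the control.
#'
#' @param a_control control absorbance (> 0).
#' @param a_sample sample absorbance (>= 0); vectorized.
#' @return percent inhibition.
#' @export
percent_inhibition <- function(a_control, a_sample) {
  stop_if_not_number(a_control, "a_control")
  stop_if_not_number(a_sample, "a_sample")
  if (any(a_control <= 0)) stop("a_control must be > 0", call. = FALSE)
  100 * (a_control - a_sample) / a_control
}

#' MTT percent cell viability from optical densities
#'
#' 100 * OD_sample / OD_control.
#'
#' @param od_sample sample optical density; vectorized.
#' @param od_control control optical density (> 0).
#' @return percent viability.
#' @export
percent_viability <- function(od_sample, od_control) {
  stop_if_not_number(od_sample, "od_sample")
  stop_if_not_number(od_control, "od_control")
  if (any(od_control <= 0)) stop("od_control must be > 0", call. = FALSE)
  100 * od_sample / od_control
}

#' Aggregate assay replicates as mean and SEM
#'
#' SEM is the sample standard deviation over sqrt(n). A single
#' replicate yields SEM 0 with a warning (no dispersion estimate).
#'
#' @param values numeric replicate values (n >= 1).
#' @return list with `mean`, `sem`, `n`.
#' @export
aggregate_replicates <- function(values) {
  if (length(values) == 0L) stop("no replicate values", call. = FALSE)
  stop_if_not_number(values, "replicates")
  n <- length(values)
  if (n == 1L) {
    warning("single replicate: SEM reported as 0")
    return(list(mean = values, sem = 0, n = 1L))
  }
  list(mean = mean(values), sem = stats::sd(values) / sqrt(n), n = n)
}

#' Read a dose-response table
#'
#' Accepts `concentration_ug_ml,response_pct` (optionally with a
#' `sem_pct` column) or `concentration_ug_ml,rep1,rep2,...` replicate
#' layouts; replicate columns are averaged into `response_pct` and kept.
#'
#' @param path TSV/CSV path.
#' @return data.frame with `concentration`, `response`, and a
#'   `replicates` matrix attribute when replicate columns were present.
#' @export
read_dose_response <- function(path) {
  df <- read_table_auto(path)
  conc <- match_column(df, c("concentration_ug_ml", "concentration", "conc"))
  if (is.null(conc)) stop("missing concentration column", call. = FALSE)
  rep_cols <- grep("^rep[0-9]+$", names(df), value = TRUE)
  resp <- match_column(df, c("response_pct", "response", "inhibition_pct"))
  if (length(rep_cols) > 0L) {
    reps <- as.matrix(df[rep_cols])
    resp <- rowMeans(reps)
  } else if (is.null(resp)) {
    stop("missing response column (response_pct or rep1..repN)", call. = FALSE)
  } else {
    reps <- NULL
  }
  out <- data.frame(concentration = as.numeric(conc),
                    response = as.numeric(resp))
  if (length(rep_cols) > 0L) attr(out, "replicates") <- reps
  out
}

#' Fit a logarithmic dose-response curve
#'
#' Ordinary least squares of response (%) on the natural log of
#' concentration: y = a*ln(x) + b. The IC50 is the concentration at
#' which the fitted response equals 50% exactly, exp((50 - b)/a). When
#' replicate responses are supplied, each replicate series is also
#' fitted separately and the SEM of the replicate IC50s is reported.
#'
#' @param data data.frame with columns `concentration` (µg/mL, > 0) and
#'   `response` (%), e.g. from [read_dose_response()]; alternatively a
#'   numeric concentration vector with `response` given separately.
#' @param response optional numeric response vector when `data` is a
#'   concentration vector.
#' @param level response level defining the inflection concentration
#'   (default 50, i.e. IC50).
#' @return object of class `log_dose_fit` with elements `a` (slope, %
#'   per ln(µg/mL)), `b` (intercept, %), `r2`, `ic50` (µg/mL),
#'   `ic50_se`, `ic50_note`, `model` (the underlying `lm`), `data`.
#' @examples
#' d <- read_dose_response(system.file("extdata", "dpph_response.tsv",
#'                                     package = "phytodock"))
#' fit <- fit_log_response(d)
#' fit
#' @export
fit_log_response <- function(data, response = NULL, level = 50) {
  if (!is.data.frame(data)) {
    data <- data.frame(concentration = as.numeric(data),
                       response = as.numeric(response))
  }
  conc <- data$concentration
  y <- data$response
  if (length(conc) < 3L) stop("need at least 3 dose-response points",
                              call. = FALSE)
  if (any(conc <= 0)) stop("concentrations must be > 0", call. = FALSE)
  if (length(unique(conc)) < 2L)
    stop("all concentrations equal: singular fit", call. = FALSE)
  lx <- log(conc)
  model <- stats::lm(y ~ lx)
  a <- unname(coef(model)[2L])
  b <- unname(coef(model)[1L])
  r2 <- if (stats::var(y) == 0) 1
        else suppressWarnings(summary(model)$r.squared)

  note <- NULL
  ic50_val <- if (a != 0) exp((level - b) / a) else NA_real_
  if (a <= 0 && min(y) < level && max(y) > level)
    note <- "non-positive slope with responses spanning the target level: IC50 unreliable"
  if (a == 0) note <- "zero slope: IC50 undefined"

  # Uncertainty: per-replicate fits when replicates exist, else the
  # delta-method SE of exp((level - b)/a) from the OLS covariance.
  reps <- attr(data, "replicates")
  if (!is.null(reps) && ncol(reps) >= 2L) {
    rep_ic50 <- apply(reps, 2L, function(col) {
      m <- stats::lm(col ~ lx)
      exp((level - coef(m)[1L]) / coef(m)[2L])
    })
    ic50_se <- stats::sd(rep_ic50) / sqrt(length(rep_ic50))
  } else if (a != 0) {
    V <- suppressWarnings(stats::vcov(model))  # order: (Intercept), lx
    g <- c(-1 / a, -(level - b) / a^2) # d(lnIC50)/d(b), d(lnIC50)/d(a)
    ic50_se <- ic50_val * sqrt(drop(t(g) %*% V %*% g))
  } else {
    ic50_se <- NA_real_
  }

  structure(list(a = a, b = b, r2 = r2, ic50 = ic50_val, ic50_se = ic50_se,
                 level = level, ic50_note = note, model = model,
                 data = data.frame(concentration = conc, response = y)),
            class = "log_dose_fit")
}

#' IC50 of a logarithmic dose-response fit
#'
#' Closed form exp((level - b)/a) for the fitted y = a*ln(x) + b.
#'
#' @param fit a `log_dose_fit`, or slope `a` when `b` is given directly.
#' @param b intercept, for direct evaluation.
#' @param level target response (default 50).
#' @return concentration in µg/mL.
#' @export
ic50 <- function(fit, b = NULL, level = 50) {
  if (inherits(fit, "log_dose_fit")) {
    a <- fit$a; b <- fit$b; level <- fit$level
  } else {
    a <- fit
  }
  if (a == 0) stop("slope is zero: IC50 undefined", call. = FALSE)
  exp((level - b) / a)
}

#' @export
print.log_dose_fit <- function(x, ...) {
  cat(sprintf("Logarithmic dose-response fit: y = %.3f*ln(x) + %.3f\n",
              x$a, x$b))
  cat(sprintf("  R2 = %.4f   IC%g = %.2f ug/mL", x$r2, x$level, x$ic50))
  if (is.finite(x$ic50_se)) cat(sprintf(" (SE %.2f)", x$ic50_se))
  cat("\n")
  if (!is.null(x$ic50_note)) cat("  note:", x$ic50_note, "\n")
  invisible(x)
}

#' @export
summary.log_dose_fit <- function(object, ...) {
  s <- summary(object$model)
  cat("Dose-response model: response ~ a*ln(concentration) + b\n")
  print(s$coefficients)
  cat(sprintf("R2 = %.4f, residual SD = %.3f on %d df\n", object$r2,
              s$sigma, s$df[2L]))
  cat(sprintf("IC%g = %.3f ug/mL\n", object$level, object$ic50))
  invisible(s)
}

#' @export
coef.log_dose_fit <- function(object, ...) {
  c(a = object$a, b = object$b)
}

#' @export
predict.log_dose_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$concentration
          else if (is.data.frame(newdata)) newdata$concentration
          else as.numeric(newdata)
  object$a * log(conc) + object$b
}

#' @export
residuals.log_dose_fit <- function(object, ...) {
  object$data$response - predict(object)
}

#' @export
plot.log_dose_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$concentration, d$response, log = "x",
                 xlab = "concentration (ug/mL)", ylab = "response (%)",
                 pch = 19, ...)
  xx <- exp(seq(log(min(d$concentration)), log(max(d$concentration)),
                length.out = 100))
  graphics::lines(xx, predict(x, xx))
  graphics::abline(h = x$level, lty = 3)
  invisible(x)
}

#' @export
simulate.log_dose_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sig <- summary(object$model)$sigma
  mu <- predict(object)
  replicate(nsim, mu + stats::rnorm(length(mu), 0, sig), simplify = FALSE)
}
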