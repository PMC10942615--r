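#' Titration schedule of an ITC experiment
#'
#' @param v0_ul Active cell volume (uL).
#' @param dv_ul Per-injection volumes (uL), one per injection.
#' @param syringe_um Titrant (syringe) concentration (uM).
#' @param cell_um Initial titrand (cell) concentration (uM).
#' @param temperature_c Temperature (degrees C), metadata only.
#' @return List of class `titration_schedule`.
#' @export
titration_schedule <- function(v0_ul = 170, dv_ul = rep(2, 20),
                               syringe_um = 300, cell_um = 35,
                               temperature_c = 25) {
  stopifnot(v0_ul > 0, all(dv_ul > 0), syringe_um > 0, cell_um > 0)
  structure(list(v0_ul = v0_ul, dv_ul = as.numeric(dv_ul),
                 syringe_um = syringe_um, cell_um = cell_um,
                 temperature_c = temperature_c),
            class = "titration_schedule")
}

#' One-site independent-binding parameters
#'
#' @param kd_um Dissociation constant (uM); `Ka = 1 / Kd` in 1/M.
#' @param dh_kcal Binding enthalpy (kcal/mol); negative = exothermic.
#' @param n Stoichiometry (default 1, the fixed value used when the
#'   titrand concentration is well determined).
#' @param dilution_offset Constant per-injection heat of dilution, in
#'   the same units as the thermogram (ucal; default 0).
#' @return List of class `one_site_params` with `ka_Minv` and `kd_um`
#'   satisfying `Ka * Kd = 1` exactly.
#' @export
one_site_params <- function(kd_um, dh_kcal, n = 1, dilution_offset = 0) {
  stopifnot(kd_um > 0, is.finite(kd_um), n > 0)
  structure(list(kd_um = kd_um, ka_Minv = 1 / (kd_um * 1e-6),
                 dh_kcal = dh_kcal, n = n,
                 dilution_offset = dilution_offset),
            class = "one_site_params")
}

## Cumulative heat content of the cell after each injection (ucal,
## calorimetric sign: exothermic negative).
## Overflow-cell dilution: with v = cumulative injected volume / V0,
##   [M]_i = M0 (1 - v/2) / (1 + v/2),   [X]_i = Xs v / (1 + v/2),
## and the bound fraction theta solves the one-site quadratic.
.itc_cumulative_heat <- function(ka, dh_kcal, n, schedule) {
  v0 <- schedule$v0_ul * 1e-6                       # L
  m0 <- schedule$cell_um * 1e-6                     # M
  xs <- schedule$syringe_um * 1e-6                  # M
  v <- cumsum(schedule$dv_ul * 1e-6) / v0
  if (any(v >= 2))
    stop("injected volume inconsistent with cell volume (depletion)",
         call. = FALSE)
  mt <- m0 * (1 - v / 2) / (1 + v / 2)
  xt <- xs * v / (1 + v / 2)
  b <- 1 + xt / (n * mt) + 1 / (n * ka * mt)
  theta <- (b - sqrt(b^2 - 4 * xt / (n * mt))) / 2
  n * theta * mt * v0 * dh_kcal * 1000 * 1e6        # ucal
}

## per-injection heats from cumulative heats with displaced-volume
## correction (trapezoidal form)
.itc_injection_heats <- function(Q, schedule) {
  v0 <- schedule$v0_ul
  Qprev <- c(0, Q[-length(Q)])
  Q - Qprev + (schedule$dv_ul / v0) * (Q + Qprev) / 2
}

#' Simulate a one-site ITC thermogram
#'
#' Generates per-injection heats from the single-site binding isotherm
#' with overflow-cell dilution and the trapezoidal displaced-volume
#' correction, plus a constant dilution offset and optional Gaussian
#' noise. With the `exothermic_positive` convention (the instrument
#' default here), heat releases are reported as positive peaks.
#'
#' @param params A [one_site_params()] list.
#' @param schedule A [titration_schedule()].
#' @param noise_sd Gaussian noise sd on per-injection heats (ucal).
#' @param seed Optional integer seed.
#' @param sign Sign convention: `"exothermic_positive"` (default) or
#'   `"exothermic_negative"`.
#' @return Object of class `thermogram`: list with `q` (ucal, in the
#'   declared convention), `schedule`, `sign`.
#' @export
simulate_titration <- function(params, schedule = titration_schedule(),
                               noise_sd = 0, seed = NULL,
                               sign = c("exothermic_positive",
                                        "exothermic_negative")) {
  stopifnot(inherits(params, "one_site_params"),
            inherits(schedule, "titration_schedule"), noise_sd >= 0)
  sign <- match.arg(sign)
  if (!is.null(seed)) set.seed(seed)
  Q <- .itc_cumulative_heat(params$ka_Minv, params$dh_kcal, params$n,
                            schedule)
  q <- .itc_injection_heats(Q, schedule) + params$dilution_offset
  if (noise_sd > 0) q <- q + stats::rnorm(length(q), 0, noise_sd)
  if (sign == "exothermic_positive") q <- -q
  structure(list(q = q, schedule = schedule, sign = sign),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat("ITC thermogram: ", length(x$q), " injections (", x$sign, ")\n",
      sep = "")
  invisible(x)
}

#' Subtract the heat of dilution estimated from the last injections
#'
#' The mean heat of the final `k_last` injections (past saturation,
#' where no further binding occurs) is subtracted from every injection.
#'
#' @param thermogram A `thermogram`.
#' @param k_last Number of trailing injections to average (default 3;
#'   must be < number of injections).
#' @return The corrected `thermogram`.
#' @export
subtract_dilution_heat <- function(thermogram, k_last = 3L) {
  stopifnot(inherits(thermogram, "thermogram"))
  n <- length(thermogram$q)
  if (k_last >= n)
    stop("k_last must be smaller than the number of injections",
         call. = FALSE)
  offset <- mean(utils::tail(thermogram$q, k_last))
  thermogram$q <- thermogram$q - offset
  thermogram$dilution_offset_subtracted <- offset
  thermogram
}

#' Fit the one-site independent-binding model to a thermogram
#'
#' Nonlinear least squares on per-injection heats normalized per mole of
#' injectant, with the stoichiometry N fixed to 1 by default.
#' The optimizer restarts from a log-spaced grid of Ka values and keeps
#' the best solution; a c-value (`N * Ka * [cell]`) outside `[0.1, 1000]`
#' is reported as a warning because the isotherm shape then constrains
#' Ka only weakly.
#'
#' @param thermogram A `thermogram` (dilution-subtracted or not; a
#'   constant offset mainly biases the tail and should be removed with
#'   [subtract_dilution_heat()] first).
#' @param schedule Optional [titration_schedule()] (defaults to the one
#'   carried by the thermogram).
#' @param fix_n Keep N fixed at `n` (default TRUE).
#' @param n Stoichiometry used (or started from) in the fit (default 1).
#' @return Object of class `itc_fit`: list with `params` (a
#'   [one_site_params()] holding the estimates, `Kd = 1/Ka` exactly),
#'   `fitted`, `residuals`, `rss`, `c_value`, `convergence` (per-start
#'   table), `thermogram`, `schedule`, `fix_n`.
#' @examples
#' tg <- simulate_titration(one_site_params(kd_um = 16.46, dh_kcal = -5))
#' fit <- fit_one_site(tg)
#' coef(fit)
#' @export
fit_one_site <- function(thermogram, schedule = NULL, fix_n = TRUE, n = 1) {
  stopifnot(inherits(thermogram, "thermogram"))
  if (is.null(schedule)) schedule <- thermogram$schedule
  q <- thermogram$q
  if (thermogram$sign == "exothermic_positive") q <- -q  # calorimetric sign
  if (length(q) < 5L)
    stop("need at least 5 injections to fit", call. = FALSE)
  if (max(abs(q)) == 0)
    stop("thermogram carries no signal; fit rejected", call. = FALSE)

  moles_inj <- schedule$syringe_um * 1e-6 * schedule$dv_ul * 1e-6  # mol
  y <- q * 1e-6 / moles_inj / 1000                                 # kcal/mol

  model <- function(log10ka, dh, nn) {
    Q <- .itc_cumulative_heat(10^log10ka, dh, nn, schedule)
    .itc_injection_heats(Q, schedule) * 1e-6 / moles_inj / 1000
  }
  dh0 <- sum(q) * 1e-6 / (schedule$cell_um * 1e-6 *
                          schedule$v0_ul * 1e-6) / 1000 / n
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -1
  starts <- seq(2, 9, length.out = 8)   # log10 Ka grid, Kd 10 mM .. 1 nM

  runs <- lapply(starts, function(s0) {
    fit <- tryCatch({
      if (fix_n)
        minpack.lm::nlsLM(y ~ model(log10ka, dh, n),
                          start = list(log10ka = s0, dh = dh0),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      else
        minpack.lm::nlsLM(y ~ model(log10ka, dh, nn),
                          start = list(log10ka = s0, dh = dh0, nn = n),
                          lower = c(-Inf, -Inf, 1e-3),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
    }, error = function(e) NULL)
    if (is.null(fit)) return(list(ok = FALSE, start = s0))
    list(ok = TRUE, start = s0, fit = fit,
         rss = sum(stats::resid(fit)^2))
  })
  ok <- vapply(runs, `[[`, logical(1L), "ok")
  if (!any(ok))
    stop("one-site fit failed to converge from every start (log10 Ka grid ",
         paste(range(starts), collapse = ".."), ")", call. = FALSE)
  best <- runs[ok][[which.min(vapply(runs[ok], `[[`, numeric(1L), "rss"))]]
  cf <- stats::coef(best$fit)
  ka <- 10^cf[["log10ka"]]
  n_hat <- if (fix_n) n else cf[["nn"]]
  est <- one_site_params(kd_um = 1 / ka * 1e6, dh_kcal = cf[["dh"]],
                         n = n_hat)
  c_value <- n_hat * ka * schedule$cell_um * 1e-6
  if (c_value < 0.1 || c_value > 1000)
    warning(sprintf("c-value %.3g outside [0.1, 1000]: Ka only weakly determined",
                    c_value), call. = FALSE)
  conv <- data.frame(start_log10ka = vapply(runs, `[[`, numeric(1L), "start"),
                     converged = ok,
                     rss = vapply(runs, function(r)
                       if (r$ok) r$rss else NA_real_, numeric(1L)))
  structure(list(params = est,
                 fitted = stats::fitted(best$fit),
                 residuals = stats::resid(best$fit),
                 rss = best$rss, c_value = c_value, convergence = conv,
                 thermogram = thermogram, schedule = schedule,
                 fix_n = fix_n, y = y),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf(
    "One-site binding fit: Kd = %.4g uM, dH = %.4g kcal/mol, N = %.3g%s (c = %.3g, rss = %.3g)\n",
    x$params$kd_um, x$params$dh_kcal, x$params$n,
    if (x$fix_n) " (fixed)" else "", x$c_value, x$rss))
  invisible(x)
}

#' @export
coef.itc_fit <- function(object, ...) {
  c(ka_Minv = object$params$ka_Minv, kd_um = object$params$kd_um,
    dh_kcal = object$params$dh_kcal, n = object$params$n)
}

#' @export
summary.itc_fit <- function(object, ...) {
  cat("One-site independent-binding model\n")
  print(object)
  cat(sprintf("  residual sd: %.3g kcal/mol injectant over %d injections\n",
              stats::sd(object$residuals), length(object$residuals)))
  cat(sprintf("  converged starts: %d / %d\n",
              sum(object$convergence$converged),
              nrow(object$convergence)))
  invisible(object)
}

#' @export
residuals.itc_fit <- function(object, ...) object$residuals

#' Predicted per-injection heats from a one-site fit
#'
#' @param object An `itc_fit`.
#' @param schedule Optional alternative [titration_schedule()].
#' @param ... Unused.
#' @return Per-injection heats normalized per mole of injectant
#'   (kcal/mol, calorimetric sign).
#' @export
predict.itc_fit <- function(object, schedule = NULL, ...) {
  if (is.null(schedule)) schedule <- object$schedule
  moles_inj <- schedule$syringe_um * 1e-6 * schedule$dv_ul * 1e-6
  Q <- .itc_cumulative_heat(object$params$ka_Minv, object$params$dh_kcal,
                            object$params$n, schedule)
  .itc_injection_heats(Q, schedule) * 1e-6 / moles_inj / 1000
}

#' Simulate thermograms from a fitted one-site model
#'
#' @param object An `itc_fit`.
#' @param nsim Number of thermograms.
#' @param seed Optional integer seed.
#' @param noise_sd Per-injection noise sd (ucal); defaults to the
#'   residual scale of the fit converted back to heat units.
#' @param ... Unused.
#' @return List of `thermogram` objects.
#' @export
simulate.itc_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sd)) {
    moles_inj <- object$schedule$syringe_um * 1e-6 *
      object$schedule$dv_ul * 1e-6
    noise_sd <- stats::sd(object$residuals * 1000 * moles_inj * 1e6)
  }
  lapply(seq_len(nsim), function(i)
    simulate_titration(object$params, object$schedule,
                       noise_sd = noise_sd, sign = object$thermogram$sign))
}

#' Binding isotherm plot of a one-site fit
#'
#' Normalized per-injection heats against the titrant/titrand mole
#' ratio, with the fitted isotherm overlaid.
#'
#' @param x An `itc_fit`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.itc_fit <- function(x, ...) {
  sch <- x$schedule
  v <- cumsum(sch$dv_ul) / sch$v0_ul
  ratio <- (sch$syringe_um * v / (1 + v / 2)) /
    (sch$cell_um * (1 - v / 2) / (1 + v / 2))
  graphics::plot(ratio, x$y, xlab = "mole ratio (titrant/titrand)",
                 ylab = "heat (kcal/mol injectant)", ...)
  graphics::lines(ratio, x$fitted, col = "red3")
  invisible(x)
}

#' Signed fold of affinity change between two Kd values
#'
#' Expresses how binding affinity changes from a reference to a
#' modulated condition: a weaker affinity (larger Kd) is reported as
#' `-(kd_modulated / kd_reference)` and a stronger one as
#' `+(kd_reference / kd_modulated)`, rounded to two decimals; identical
#' affinities give +1. The magnitude is therefore always >= 1.
#'
#' @param kd_reference,kd_modulated Positive Kd values (same units).
#' @return Signed fold, rounded to 2 decimals.
#' @examples
#' fold_affinity_change(16.46, 531.55)  # -32.29
#' fold_affinity_change(3.64, 2.14)     # +1.70
#' @export
fold_affinity_change <- function(kd_reference, kd_modulated) {
  if (kd_reference <= 0 || kd_modulated <= 0)
    stop("Kd values must be positive", call. = FALSE)
  fold <- if (kd_modulated > kd_reference)
    -(kd_modulated / kd_reference) else kd_reference / kd_modulated
  round(fold, 2)
}

#' Compare replicate affinities with an unpaired t-test
#'
#' Two-sided unpaired Student's t-test (equal variances) on replicate Kd
#' values from two conditions.
#'
#' @param kds_a,kds_b Numeric replicate vectors, each n >= 2.
#' @return Two-sided p-value.
#' @export
compare_affinities <- function(kds_a, kds_b) {
  if (length(kds_a) < 2L || length(kds_b) < 2L)
    stop("each condition needs at least 2 replicate Kd values",
         call. = FALSE)
  if (stats::sd(kds_a) == 0 && stats::sd(kds_b) == 0)
    return(if (mean(kds_a) == mean(kds_b)) 1 else 0)
  stats::t.test(kds_a, kds_b, var.equal = TRUE)$p.value
}

#' Read a thermogram CSV
#'
#' Dialect: metadata header lines `# v0_ul=`, `# syringe_um=`,
#' `# cell_um=`, `# sign=` followed by a CSV table with header
#' `injection,dv_ul,heat`.
#'
#' @param path CSV path.
#' @return A `thermogram` (heats in the declared sign convention).
#' @export
read_thermogram_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=")[[1]]
    meta[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  need <- c("v0_ul", "syringe_um", "cell_um", "sign")
  if (!all(need %in% names(meta)))
    stop("thermogram CSV missing metadata line(s): ",
         paste(setdiff(need, names(meta)), collapse = ", "), call. = FALSE)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  if (!identical(names(df), c("injection", "dv_ul", "heat")))
    stop("thermogram CSV must have header injection,dv_ul,heat",
         call. = FALSE)
  sch <- titration_schedule(v0_ul = as.numeric(meta$v0_ul),
                            dv_ul = df$dv_ul,
                            syringe_um = as.numeric(meta$syringe_um),
                            cell_um = as.numeric(meta$cell_um))
  structure(list(q = df$heat, schedule = sch, sign = meta$sign),
            class = "thermogram")
}

#' Write a thermogram CSV
#'
#' @param thermogram A `thermogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thermogram_csv <- function(thermogram, path) {
  sch <- thermogram$schedule
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# v0_ul=%g", sch$v0_ul),
               sprintf("# syringe_um=%g", sch$syringe_um),
               sprintf("# cell_um=%g", sch$cell_um),
               sprintf("# sign=%s", thermogram$sign)), con)
  utils::write.csv(data.frame(injection = seq_along(thermogram$q),
                              dv_ul = sch$dv_ul,
                              heat = sprintf("%.6g", thermogram$q)),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
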