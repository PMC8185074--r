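## Dose-response fitting: four-parameter logistic with the bottom fixed
## at 0 and the top constrained below 120, by bounded nonlinear least
## squares with a deterministic multi-start grid.

#' Fit an IC50 from a dose-response table
#'
#' Fits `Y = (Top) / (1 + 10^((log10(IC50) - X) * Hill))` (bottom fixed
#' at 0, top < 120) to % activity data by nonlinear least squares,
#' multi-started from a fixed grid of IC50 guesses spanning the observed
#' concentration range (deciles) and Hill starts of -1 and +1.
#'
#' @param data a `DoseResponse` data.frame (columns concentration_M,
#'   activity_pct, optional replicate) or any data.frame with those
#'   columns
#' @param average_replicates average activities per concentration before
#'   fitting (per-replicate points fit jointly otherwise)
#' @return a `FitResult`: ic50 (molar), hill_slope, top, bottom (0),
#'   covariance (free parameters, log10-ic50 space), converged, sse
#' @export
fit_ic50 <- function(data, average_replicates = TRUE) {
  conc <- data$concentration_M
  act <- data$activity_pct
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (length(unique(conc)) < 4)
    stop("need at least 4 distinct concentrations")
  if (average_replicates && !is.null(data$replicate)) {
    agg <- stats::aggregate(act, list(conc = conc), mean)
    conc <- agg$conc; act <- agg$x
  }
  if (diff(range(act)) < 1e-9)
    stop("degenerate fit: all activities equal")
  x <- log10(conc)
  resid_fn <- function(par) {
    act - par["top"] / (1 + 10^((par["lic50"] - x) * par["hill"]))
  }
  lower <- c(lic50 = min(x) - 3, hill = -10, top = 1e-6)
  upper <- c(lic50 = max(x) + 3, hill = 10, top = 120 - 1e-9)
  starts <- expand.grid(
    lic50 = quantile(x, seq(0.1, 0.9, by = 0.2), names = FALSE),
    hill = c(-1, 1),
    top = min(max(act), 100))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(par = unlist(starts[s, ]), fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best_sse) { best <- fit; best_sse <- sse }
  }
  if (is.null(best)) stop("IC50 fit failed from every start")
  par <- best$par
  covar <- tryCatch({
    dof <- length(x) - 3
    if (dof > 0) sum(best$fvec^2) / dof * solve(best$hessian) else NULL
  }, error = function(e) NULL)
  structure(list(ic50 = 10^unname(par["lic50"]),
                 hill_slope = unname(par["hill"]),
                 top = unname(par["top"]), bottom = 0,
                 covariance = covar,
                 converged = best$info %in% 1:4,
                 sse = best_sse,
                 n_points = length(x)),
            class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult: IC50 = %.3g M, Hill = %.3f, Top = %.1f%%%s\n",
              x$ic50, x$hill_slope, x$top,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Selectivity fold between two IC50s
#'
#' `ic50_b / ic50_a`: how many times more potent the compound is against
#' target a than against target b.
#'
#' @param ic50_a,ic50_b IC50 values (molar), both positive
#' @return unitless fold
#' @export
selectivity <- function(ic50_a, ic50_b) {
  if (ic50_a <= 0 || ic50_b <= 0) stop("IC50 values must be positive")
  ic50_b / ic50_a
}
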