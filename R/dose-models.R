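#' Calibrate the Hill dose-occupancy model
#'
#' One-parameter Hill relation `Occ(%) = 100 * Dose / (ED50 + Dose)` with
#' the asymptote fixed at 100%. With a single (dose, occupancy) pair the
#' half-occupancy dose is obtained algebraically,
#' `ED50 = Dose * (100 - Occ) / Occ`; with several pairs it minimizes the
#' unweighted squared error in occupancy space.
#'
#' @param doses doses (ug/kg, > 0).
#' @param occupancies observed occupancies (%).
#' @return An object of class `hill_model`: list with `ed50` (ug/kg),
#'   `rss`, `n`.
#' @examples
#' fit_hill(30, 57)$ed50  # 22.63 ug/kg
#' @export
fit_hill <- function(doses, occupancies) {
  if (length(doses) != length(occupancies) || length(doses) < 1) {
    stop("need >= 1 (dose, occupancy) pair", call. = FALSE)
  }
  if (any(doses <= 0)) stop("doses must be > 0", call. = FALSE)
  if (length(doses) == 1) {
    if (occupancies <= 0 || occupancies >= 100) {
      stop("single-pair inversion requires occupancy strictly in (0, 100)",
           call. = FALSE)
    }
    ed50 <- doses * (100 - occupancies) / occupancies
    return(structure(list(ed50 = ed50, rss = 0, n = 1L),
                     class = "hill_model"))
  }
  rss_fn <- function(log_ed50) {
    pred <- 100 * doses / (exp(log_ed50) + doses)
    sum((occupancies - pred)^2)
  }
  opt <- stats::optimize(rss_fn, c(log(1e-4), log(1e6)), tol = 1e-12)
  structure(list(ed50 = exp(opt$minimum), rss = opt$objective,
                 n = length(doses)),
            class = "hill_model")
}

#' Calibrate the exponential occupancy-washout model
#'
#' Fits `Occ(%) = Occ_Day0 * exp(-lambda * Day)` by nonlinear least squares
#' in the natural (percentage) scale, with a log-linear ordinary least
#' squares fit used only to initialize. Fitting in natural scale avoids the
#' bias a log-scale fit acquires from noise near zero.
#'
#' @param days days since treatment (>= 2 points over >= 2 distinct days).
#' @param occupancies observed occupancies (%). Non-positive values are
#'   dropped (with a warning) before the log-scale initialization only.
#' @return An object of class `decay_model`: list with `occ_day0` (%),
#'   `lambda` (1/day), `rss`, `n`.
#' @examples
#' fit <- fit_decay(c(0, 1), c(78, 48))
#' c(fit$occ_day0, fit$lambda)  # 78, log(78/48)
#' @export
fit_decay <- function(days, occupancies) {
  if (length(days) != length(occupancies) || length(days) < 2 ||
      length(unique(days)) < 2) {
    stop("need >= 2 points spanning >= 2 distinct days", call. = FALSE)
  }
  pos <- occupancies > 0
  if (!all(pos)) {
    warning("dropping non-positive occupancies for log-scale initialization")
  }
  starts <- list(list(occ_day0 = min(99.5, max(0.5, max(occupancies))),
                      lambda = 0.5))
  if (sum(pos) >= 2 && length(unique(days[pos])) >= 2) {
    init <- stats::lm(log(occupancies[pos]) ~ days[pos])
    # keep the start strictly inside the bounds: a start pinned on a bound
    # can leave the Levenberg-Marquardt step projected onto it
    starts <- c(list(list(
      occ_day0 = min(99.5, max(0.5, exp(stats::coef(init)[[1]]))),
      lambda = max(0, -stats::coef(init)[[2]]))), starts)
  }
  df <- data.frame(day = days, occ = occupancies)
  best <- NULL
  for (start in starts) {
    fit <- tryCatch(minpack.lm::nlsLM(
      occ ~ occ_day0 * exp(-lambda * day), data = df, start = start,
      lower = c(occ_day0 = 0, lambda = 0),
      upper = c(occ_day0 = 100, lambda = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("decay fit failed to converge", call. = FALSE)
  co <- stats::coef(best$fit)
  structure(list(occ_day0 = unname(co["occ_day0"]),
                 lambda = unname(co["lambda"]),
                 rss = best$rss, n = length(days)),
            class = "decay_model")
}

#' Predict occupancy from a calibrated dose or washout model
#'
#' @param model a `hill_model` or `decay_model`.
#' @param at dose (ug/kg) for a Hill model, day for a decay model; >= 0.
#' @return predicted occupancy (%).
#' @examples
#' predict_occupancy(fit_hill(30, 57), 100)  # ~81.5
#' @export
predict_occupancy <- function(model, at) {
  if (any(at < 0)) stop("dose/day must be >= 0", call. = FALSE)
  if (inherits(model, "hill_model")) {
    100 * at / (model$ed50 + at)
  } else if (inherits(model, "decay_model")) {
    model$occ_day0 * exp(-model$lambda * at)
  } else {
    stop("model must be a hill_model or decay_model", call. = FALSE)
  }
}

#' @export
print.hill_model <- function(x, ...) {
  cat(sprintf("Hill dose-occupancy model: ED50 = %.3f ug/kg (RSS %.4g, n = %d)\n",
              x$ed50, x$rss, x$n))
  invisible(x)
}

#' @export
print.decay_model <- function(x, ...) {
  cat(sprintf(
    "Occupancy washout model: Occ_Day0 = %.2f%%, lambda = %.4f /day (RSS %.4g)\n",
    x$occ_day0, x$lambda, x$rss))
  invisible(x)
}
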