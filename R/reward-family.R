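# Inverse reward-size model family. Refusal rate E as a function of reward
# size R (drops): E = 1/(a R) + e, with four nested sharing structures for
# the condition dependence of incentive impact a and intercept e:
#   #1  a per condition, e = 0
#   #2  a per condition, e shared
#   #3  a shared,        e per condition
#   #4  a per condition, e per condition

# Gaussian log-likelihood at the MLE sigma, with a variance floor so exact
# fits stay finite and BIC ties resolve by parameter count.
gauss_loglik <- function(rss, n) {
  sigma2 <- max(rss / n, 1e-12)
  -n / 2 * (log(2 * pi * sigma2) + 1)
}

reward_model_defs <- list(
  list(id = 1L, structure = "a(cond), e = 0",      a_by_cond = TRUE,  e_mode = "zero"),
  list(id = 2L, structure = "a(cond), shared e",   a_by_cond = TRUE,  e_mode = "shared"),
  list(id = 3L, structure = "shared a, e(cond)",   a_by_cond = FALSE, e_mode = "by_cond"),
  list(id = 4L, structure = "a(cond), e(cond)",    a_by_cond = TRUE,  e_mode = "by_cond")
)

#' Fit and compare the inverse reward-size model family
#'
#' Fits the refusal-rate model `E = clip(1/(a R) + e, 0, 1)` over reward
#' sizes `R` under four nested condition-sharing structures (see Details)
#' by maximum likelihood, and selects the best structure by BIC.
#'
#' The binomial likelihood treats each cell's refusal count as
#' `Binomial(presentations, E)` and uses total presentations as the BIC
#' sample size; the gaussian likelihood is least squares on cell rates with
#' the number of cells as sample size (mirroring mixed-model practice, at
#' the cost of ignoring cell precision).
#'
#' @param refusals refusal table (see [aggregate_refusal()]) with columns
#'   `condition`, `level` (reward size, drops), `refusals`,
#'   `presentations`; rows are summed into condition x level cells.
#' @param likelihood `"binomial"` (default) or `"gaussian"`.
#' @param control label of the control condition used to normalize the
#'   incentive impact; defaults to `"CON"` when present, else the first
#'   condition.
#' @return An object of class `reward_family_fit`: list with `models`
#'   (per structure: parameters, logL, parameter count, BIC, convergence),
#'   `selected` (model id with minimal BIC, ties to fewer parameters),
#'   `a` and `e` per condition from the selected model, and
#'   `normalized_a = a / a_control`.
#' @examples
#' cfg <- behavior_sim_config("reward_size",
#'   conditions = data.frame(condition = c("CON", "HO"), a = c(8, 4),
#'                           e = c(0, 0)),
#'   trials_per_cell = 400, seed = 3)
#' fam <- fit_reward_size_family(aggregate_refusal(gen_reward_size_sessions(cfg)))
#' fam$selected; fam$normalized_a
#' @export
fit_reward_size_family <- function(refusals,
                                   likelihood = c("binomial", "gaussian"),
                                   control = NULL) {
  likelihood <- match.arg(likelihood)
  stopifnot(all(c("condition", "level", "refusals", "presentations")
                %in% names(refusals)))
  key <- interaction(refusals$condition, refusals$level, drop = TRUE)
  cells <- data.frame(
    condition = tapply(as.character(refusals$condition), key, `[`, 1),
    R = as.numeric(tapply(refusals$level, key, `[`, 1)),
    k = as.numeric(tapply(refusals$refusals, key, sum)),
    n = as.numeric(tapply(refusals$presentations, key, sum))
  )
  if (length(unique(cells$R)) < 2) {
    stop("need >= 2 reward levels", call. = FALSE)
  }
  conds <- unique(cells$condition)
  ci <- match(cells$condition, conds)
  C <- length(conds)
  n_bic <- if (likelihood == "binomial") sum(cells$n) else nrow(cells)

  predict_cells <- function(a_vec, e_vec) {
    clip01(1 / (a_vec[ci] * cells$R) + e_vec[ci])
  }
  objective <- function(a_vec, e_vec) {
    p <- predict_cells(a_vec, e_vec)
    if (likelihood == "binomial") {
      p <- pmin(1 - 1e-6, pmax(1e-6, p))
      -sum(cells$k * log(p) + (cells$n - cells$k) * log(1 - p))
    } else {
      sum((cells$k / cells$n - p)^2)
    }
  }

  expand_theta <- function(def, theta) {
    na <- if (def$a_by_cond) C else 1L
    a_vec <- exp(theta[seq_len(na)])
    if (!def$a_by_cond) a_vec <- rep(a_vec, C)
    e_vec <- switch(def$e_mode,
                    zero = rep(0, C),
                    shared = rep(theta[na + 1L], C),
                    by_cond = theta[na + seq_len(C)])
    list(a = a_vec, e = e_vec)
  }

  fit_one <- function(def, extra_starts = list()) {
    na <- if (def$a_by_cond) C else 1L
    ne <- switch(def$e_mode, zero = 0L, shared = 1L, by_cond = C)
    lower <- c(rep(log(1e-3), na), rep(0, ne))
    upper <- c(rep(log(1e3), na), rep(1, ne))
    fn <- function(theta) {
      pe <- expand_theta(def, theta)
      objective(pe$a, pe$e)
    }
    starts <- c(lapply(c(0.5, 2, 8), function(a0) {
      c(rep(log(a0), na), rep(0.02, ne))
    }), extra_starts)
    best <- NULL
    best_ok_value <- Inf
    for (s in starts) {
      opt <- tryCatch(
        stats::optim(s, fn, method = "L-BFGS-B", lower = lower,
                     upper = upper, control = list(maxit = 500)),
        error = function(e) NULL)
      if (is.null(opt)) next
      if (opt$convergence == 0) best_ok_value <- min(best_ok_value,
                                                     opt$value)
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (is.null(best)) return(NULL)
    # a start seeded at the optimum can abort its line search; the fit is
    # still converged if a converged start reached the same minimum
    converged <- best$convergence == 0 ||
      best_ok_value <= best$value + 1e-6
    pe <- expand_theta(def, best$par)
    logl <- if (likelihood == "binomial") -best$value else {
      gauss_loglik(best$value, nrow(cells))
    }
    p_count <- na + ne + if (likelihood == "gaussian") 1L else 0L
    list(id = def$id, structure = def$structure,
         a = stats::setNames(pe$a, conds), e = stats::setNames(pe$e, conds),
         logL = logl, n_params = p_count, n = n_bic,
         bic = p_count * log(n_bic) - 2 * logl,
         converged = converged, theta = best$par)
  }

  fits <- list()
  for (def in reward_model_defs[1:3]) fits[[def$id]] <- fit_one(def)
  # seed the full model from the nested solutions so logL(#4) >= nested logL
  extra4 <- Filter(Negate(is.null), lapply(fits[1:3], function(f) {
    if (is.null(f)) return(NULL)
    c(log(pmin(1e3, pmax(1e-3, f$a))), pmin(1, pmax(0, f$e)))
  }))
  fits[[4L]] <- fit_one(reward_model_defs[[4L]], extra_starts = extra4)

  ok <- vapply(fits, function(f) !is.null(f) && isTRUE(f$converged),
               logical(1))
  if (!all(ok)) warning("some model fits failed to converge; excluded ",
                        "from selection")
  bics <- vapply(fits, function(f) if (is.null(f)) Inf else f$bic,
                 numeric(1))
  bics[!ok] <- Inf
  npar <- vapply(fits, function(f) if (is.null(f)) Inf else f$n_params,
                 numeric(1))
  cand <- which(bics <= min(bics) + 1e-6)
  selected <- cand[which.min(npar[cand])]

  if (is.null(control)) {
    control <- if ("CON" %in% conds) "CON" else conds[1]
  }
  if (!control %in% conds) stop("control condition not found", call. = FALSE)
  sel <- fits[[selected]]
  structure(
    list(models = fits, selected = sel$id, likelihood = likelihood,
         control = control, conditions = conds,
         a = sel$a, e = sel$e,
         normalized_a = sel$a / sel$a[[control]],
         cells = cells),
    class = "reward_family_fit"
  )
}

#' @export
print.reward_family_fit <- function(x, ...) {
  cat("Inverse reward-size model family (", x$likelihood,
      " likelihood)\n", sep = "")
  for (f in x$models) {
    if (is.null(f)) next
    cat(sprintf("  #%d %-20s logL %10.2f  p %2d  BIC %10.2f%s\n",
                f$id, f$structure, f$logL, f$n_params, f$bic,
                if (f$id == x$selected) "  <- selected" else ""))
  }
  cat("a:", paste(sprintf("%s=%.3f", names(x$a), x$a), collapse = ", "),
      "\n")
  invisible(x)
}

#' Model-comparison table for a fitted family
#'
#' @param fit a `reward_family_fit`, `cost_family_fit` or
#'   `rt_relation_fit`.
#' @return data.frame with one row per model/variant: `model`, `structure`,
#'   `n_params`, `logL`, `BIC`, `delta_BIC`, `selected`.
#' @export
model_comparison_table <- function(fit) {
  entries <- if (inherits(fit, "reward_family_fit")) fit$models else
    fit$variants
  rows <- lapply(entries, function(f) {
    if (is.null(f)) return(NULL)
    data.frame(model = f$id, structure = f$structure,
               n_params = f$n_params, logL = f$logL, BIC = f$bic)
  })
  out <- do.call(rbind, rows)
  out$delta_BIC <- out$BIC - min(out$BIC)
  out$selected <- out$model == fit$selected
  out
}
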