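# Linear cost-discounting family. Refusal rate against remaining cost
# units CU for work and delay trials:
#   E_w = k_w CU + E0,   E_d = k_d CU + E0
# with the intercept E0 constrained equal across the two trial types.
# Variants differ in how the coefficients vary across conditions and
# subjects; each variant is fitted as independent least-squares fits per
# faceting unit and its BIC is the sum over units.

cost_variant_defs <- list(
  list(id = 1L, structure = "(CU_w + CU_d + E0 | monkey:cond)",
       group = c("monkey", "condition")),
  list(id = 2L, structure = "(CU_w + CU_d + E0 | cond)",
       group = "condition"),
  list(id = 3L, structure = "(CU_w + CU_d + E0 | monkey)",
       group = "monkey"),
  list(id = 4L, structure = "pooled CU_w + CU_d + E0",
       group = character(0))
)

fit_cost_unit <- function(unit) {
  cu_w <- unit$level * (unit$trial_type == "work")
  cu_d <- unit$level * (unit$trial_type == "delay")
  fit <- stats::lm(unit$refusal_rate ~ cu_w + cu_d)
  co <- stats::coef(fit)
  pred <- stats::fitted(fit)
  list(e0 = unname(co[1]), k_w = unname(co["cu_w"]),
       k_d = unname(co["cu_d"]),
       rss = sum(stats::resid(fit)^2), n = nrow(unit),
       out_of_range = any(pred < 0 | pred > 1))
}

#' Fit and compare the linear cost-discounting model family
#'
#' Fits refusal rate as a linear function of remaining cost units with
#' trial-type-specific slopes (workload `k_w`, delay `k_d`) and a single
#' intercept `E0` shared across trial types, under four faceting variants:
#' separate coefficients per subject x condition, per condition, per
#' subject, or fully pooled. Each variant's BIC is the sum of the BICs of
#' its per-unit least-squares fits, and the variant with minimal total BIC
#' is selected.
#'
#' @param refusals refusal table with columns `monkey`, `condition`,
#'   `trial_type` (`"work"`/`"delay"`), `level` (remaining CU) and
#'   `refusal_rate`. Both trial types and >= 2 CU levels are required.
#' @return An object of class `cost_family_fit`: `variants` (per variant:
#'   per-unit coefficient table, summed logL/BIC), `selected`,
#'   `params` — per-condition `k_w`, `k_d`, `E0` (subject x condition fits
#'   averaged over subjects), and `out_of_range` flag when any fitted rate
#'   falls outside \[0, 1\] at an observed CU.
#' @export
fit_cost_family <- function(refusals) {
  need <- c("monkey", "condition", "trial_type", "level", "refusal_rate")
  stopifnot(all(need %in% names(refusals)))
  refusals <- refusals[refusals$trial_type %in% c("work", "delay"), ,
                       drop = FALSE]
  if (!all(c("work", "delay") %in% refusals$trial_type)) {
    stop("both work and delay trial types are required", call. = FALSE)
  }
  if (length(unique(refusals$level)) < 2) {
    stop("need >= 2 cost-unit levels", call. = FALSE)
  }

  fit_variant <- function(def) {
    units <- if (length(def$group) == 0) list(all = refusals) else
      split(refusals, refusals[def$group], drop = TRUE)
    per_unit <- lapply(units, fit_cost_unit)
    logl <- sum(vapply(per_unit, function(u) gauss_loglik(u$rss, u$n),
                       numeric(1)))
    # per unit: 3 coefficients + residual SD
    p_count <- 4L * length(per_unit)
    bic <- sum(vapply(per_unit, function(u) {
      4 * log(u$n) - 2 * gauss_loglik(u$rss, u$n)
    }, numeric(1)))
    tab <- do.call(rbind, lapply(names(per_unit), function(nm) {
      u <- per_unit[[nm]]
      data.frame(unit = nm, k_w = u$k_w, k_d = u$k_d, e0 = u$e0,
                 n = u$n, stringsAsFactors = FALSE)
    }))
    list(id = def$id, structure = def$structure, group = def$group,
         units = tab, logL = logl, n_params = p_count, bic = bic,
         out_of_range = any(vapply(per_unit, `[[`, logical(1),
                                   "out_of_range")))
  }

  variants <- lapply(cost_variant_defs, fit_variant)
  bics <- vapply(variants, `[[`, numeric(1), "bic")
  npar <- vapply(variants, `[[`, numeric(1), "n_params")
  cand <- which(bics <= min(bics) + 1e-6)
  selected <- variants[[cand[which.min(npar[cand])]]]$id

  # per-condition parameters: subject x condition fits averaged by condition
  by_mc <- split(refusals, refusals[c("monkey", "condition")], drop = TRUE)
  mc_tab <- do.call(rbind, lapply(names(by_mc), function(nm) {
    u <- fit_cost_unit(by_mc[[nm]])
    data.frame(condition = by_mc[[nm]]$condition[1],
               monkey = by_mc[[nm]]$monkey[1],
               k_w = u$k_w, k_d = u$k_d, e0 = u$e0,
               stringsAsFactors = FALSE)
  }))
  params <- do.call(rbind, lapply(split(mc_tab, mc_tab$condition),
                                  function(d) {
    data.frame(condition = d$condition[1], k_w = mean(d$k_w),
               k_d = mean(d$k_d), e0 = mean(d$e0),
               stringsAsFactors = FALSE)
  }))
  rownames(params) <- NULL

  if (any(vapply(variants, `[[`, logical(1), "out_of_range"))) {
    warning("fitted refusal rate outside [0, 1] at an observed CU; ",
            "linear fit retained")
  }
  structure(
    list(variants = variants, selected = selected, params = params,
         subject_params = mc_tab),
    class = "cost_family_fit"
  )
}

#' @export
print.cost_family_fit <- function(x, ...) {
  cat("Linear cost-discounting family\n")
  for (v in x$variants) {
    cat(sprintf("  #%d %-32s p %3d  BIC %10.2f%s\n", v$id, v$structure,
                v$n_params, v$bic,
                if (v$id == x$selected) "  <- selected" else ""))
  }
  print(x$params, row.names = FALSE)
  invisible(x)
}
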