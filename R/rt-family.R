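# Refusal-rate / reaction-time relation. Mean RT of correct trials in a
# cell regressed on the cell's refusal rate, under nested grouping
# variants (random-effect analogs): pooled, per subject, per condition,
# per subject x condition. As in the cost family, grouped variants are
# independent per-group OLS fits with BIC summed over groups.

rt_variant_defs <- list(
  list(id = 1L, structure = "Rt ~ E (pooled)", group = character(0)),
  list(id = 2L, structure = "(Rt ~ E | monkey)", group = "monkey"),
  list(id = 3L, structure = "(Rt ~ E | cond)", group = "condition"),
  list(id = 4L, structure = "(Rt ~ E | monkey:cond)",
       group = c("monkey", "condition"))
)

#' Fit and compare the refusal-rate vs reaction-time relation family
#'
#' Regresses per-cell mean reaction time on per-cell refusal rate under
#' four nested grouping variants and selects by BIC. Grouping columns
#' absent from the input (e.g. a single-subject table) make the
#' corresponding variants infeasible; they are excluded from selection.
#'
#' @param refusals refusal table with columns `refusal_rate` and
#'   `mean_rt_ms` (cells without a mean RT are dropped), plus `monkey` /
#'   `condition` for the grouped variants.
#' @return An object of class `rt_relation_fit`: `variants` (per variant:
#'   per-group `slope` ms per unit refusal rate and `intercept` ms, summed
#'   logL/BIC), `selected`, and `slope`/`intercept` of the selected
#'   variant (per group when a grouped variant wins).
#' @export
fit_rt_relation_family <- function(refusals) {
  stopifnot(all(c("refusal_rate", "mean_rt_ms") %in% names(refusals)))
  cells <- refusals[!is.na(refusals$mean_rt_ms) &
                      !is.na(refusals$refusal_rate), , drop = FALSE]
  if (nrow(cells) < 3) stop("need >= 3 cells with both E and mean RT",
                            call. = FALSE)

  fit_variant <- function(def) {
    if (!all(def$group %in% names(cells))) return(NULL)
    units <- if (length(def$group) == 0) list(all = cells) else
      split(cells, cells[def$group], drop = TRUE)
    if (any(vapply(units, nrow, integer(1)) < 3)) return(NULL)
    per_unit <- lapply(units, function(u) {
      fit <- stats::lm(mean_rt_ms ~ refusal_rate, data = u)
      co <- stats::coef(fit)
      list(intercept = unname(co[1]), slope = unname(co[2]),
           rss = sum(stats::resid(fit)^2), n = nrow(u))
    })
    logl <- sum(vapply(per_unit, function(u) gauss_loglik(u$rss, u$n),
                       numeric(1)))
    p_count <- 3L * length(per_unit)  # slope, intercept, residual SD
    bic <- sum(vapply(per_unit, function(u) {
      3 * log(u$n) - 2 * gauss_loglik(u$rss, u$n)
    }, numeric(1)))
    coefs <- do.call(rbind, lapply(names(per_unit), function(nm) {
      data.frame(group = nm, slope = per_unit[[nm]]$slope,
                 intercept = per_unit[[nm]]$intercept,
                 stringsAsFactors = FALSE)
    }))
    list(id = def$id, structure = def$structure, group = def$group,
         coefs = coefs, logL = logl, n_params = p_count, bic = bic)
  }

  variants <- lapply(rt_variant_defs, fit_variant)
  feasible <- !vapply(variants, is.null, logical(1))
  if (!any(feasible)) stop("no feasible RT-relation variant", call. = FALSE)
  bics <- vapply(variants, function(v) if (is.null(v)) Inf else v$bic,
                 numeric(1))
  npar <- vapply(variants, function(v) if (is.null(v)) Inf else v$n_params,
                 numeric(1))
  cand <- which(bics <= min(bics) + 1e-6)
  sel_idx <- cand[which.min(npar[cand])]
  sel <- variants[[sel_idx]]
  structure(
    list(variants = variants[feasible], selected = sel$id,
         slope = stats::setNames(sel$coefs$slope, sel$coefs$group),
         intercept = stats::setNames(sel$coefs$intercept, sel$coefs$group),
         grouping = if (length(sel$group) == 0) "none" else
           paste(sel$group, collapse = ":")),
    class = "rt_relation_fit"
  )
}

#' @export
print.rt_relation_fit <- function(x, ...) {
  cat("Refusal-rate vs RT relation family\n")
  for (v in x$variants) {
    cat(sprintf("  #%d %-24s p %2d  BIC %10.2f%s\n", v$id, v$structure,
                v$n_params, v$bic,
                if (v$id == x$selected) "  <- selected" else ""))
  }
  invisible(x)
}
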