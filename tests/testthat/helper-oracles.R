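# Independent oracles used to validate the package's numerics. These
# deliberately reimplement the quantities being tested with different
# algorithms (direct quadrature, closed forms, generic optimizers).

# Direct trapezoidal evaluation of the SRTM solution
#   Ct(T) = R1 Cr(T) + (k2 - R1 k2a) * int_0^T Cr(s) exp(-k2a (T - s)) ds
# on a dense grid, one explicit integral per output time.
oracle_srtm_tac <- function(t_out, ref_fun, r1, k2, bp_nd, dt = 0.01) {
  k2a <- k2 / (1 + bp_nd)
  s <- seq(0, max(t_out), by = dt)
  cr <- ref_fun(s)
  vapply(t_out, function(T) {
    idx <- s <= T + 1e-12
    si <- s[idx]
    fi <- cr[idx] * exp(-k2a * (T - si))
    integ <- if (length(si) > 1) {
      sum((fi[-1] + fi[-length(fi)]) / 2 * diff(si))
    } else 0
    r1 * ref_fun(T) + (k2 - r1 * k2a) * integ
  }, numeric(1))
}

# Direct 3-parameter nonlinear least squares for SRTM: same weighted
# objective as the basis-function fit but optimized jointly over
# (R1, k2, BP_ND) with Nelder-Mead, independent of the grid + 1-D
# refinement scheme under test.
oracle_srtm_nls <- function(target, reference, start = c(1, 0.1, 1.5)) {
  tmid <- (target$frame_start_min + target$frame_end_min) / 2
  w <- target$frame_end_min - target$frame_start_min
  w <- w / sum(w)
  obj <- function(par) {
    if (par[2] <= 0 || par[3] < 0) return(1e10)
    pred <- srtm_forward(tmid, reference$activity_kbq_ml,
                         par[1], par[2], par[3])
    sum(w * (target$activity_kbq_ml - pred)^2)
  }
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  list(r1 = opt$par[1], k2 = opt$par[2], bp_nd = opt$par[3],
       rss = opt$value)
}

# Closed-form simple linear regression (normal equations).
oracle_ols <- function(x, y) {
  sx <- x - mean(x)
  slope <- sum(sx * (y - mean(y))) / sum(sx^2)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Small reward-size refusal table built directly from rates (no sampling).
rates_to_refusal_table <- function(rates_by_cond, sizes, n = 1000L) {
  rows <- list()
  for (cond in names(rates_by_cond)) {
    rows[[cond]] <- data.frame(
      monkey = "SIM", condition = cond, level = sizes,
      refusals = as.integer(round(rates_by_cond[[cond]] * n)),
      presentations = n, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$refusal_rate <- tab$refusals / tab$presentations
  rownames(tab) <- NULL
  tab
}
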