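#' Build a constant-fold dilution series
#'
#' `c_i = top / fold^i` for `i = 0..n_points-1`; the conventional assay
#' design is 10 points at 3-fold dilution.
#'
#' @param top highest concentration (> 0).
#' @param n_points number of points (>= 2), default 10.
#' @param fold dilution factor (> 1), default 3.
#' @return Strictly decreasing numeric vector of concentrations.
#' @export
make_dilution_series <- function(top, n_points = 10L, fold = 3) {
  if (!is.numeric(top) || top <= 0) svt_stop("top concentration must be > 0")
  if (!is.numeric(fold) || fold <= 1) svt_stop("fold must be > 1")
  if (!is.numeric(n_points) || n_points < 2) svt_stop("n_points must be >= 2")
  top / fold^(seq_len(n_points) - 1)
}

#' Construct a dose-response series
#'
#' @param drug_id,target_id identifiers.
#' @param concentrations numeric vector (one concentration per column of
#'   `responses`).
#' @param responses numeric matrix, replicates x concentrations (a vector is
#'   taken as one replicate).
#' @param units concentration units label, default `"ug/mL"`.
#' @return Object of class `dose_response_series`.
#' @export
dose_response_series <- function(drug_id, target_id, concentrations, responses,
                                 units = "ug/mL") {
  if (is.vector(responses)) responses <- matrix(responses, nrow = 1)
  if (ncol(responses) != length(concentrations)) {
    svt_stop("responses must have one column per concentration")
  }
  if (any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    svt_stop("concentrations must be positive and finite")
  }
  structure(list(drug_id = drug_id, target_id = target_id,
                 concentrations = as.numeric(concentrations),
                 responses = responses,
                 n_replicates = nrow(responses), units = units),
            class = "dose_response_series")
}

#' @export
print.dose_response_series <- function(x, ...) {
  cat(sprintf("<dose_response_series %s/%s: %d points x %d replicates (%s)>\n",
              x$drug_id, x$target_id, length(x$concentrations),
              x$n_replicates, x$units))
  invisible(x)
}

#' Read dose-response series from CSV
#'
#' @param path CSV with columns `drug_id`, `target_id`, `replicate`,
#'   `concentration`, `activity_pct`.
#' @param units concentration units label.
#' @return Named list of [dose_response_series()], one per (drug, target).
#' @export
read_dose_response <- function(path, units = "ug/mL") {
  if (!file.exists(path)) svt_stop(paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cols(df, c("drug_id", "target_id", "replicate", "concentration",
                    "activity_pct"), "dose-response table")
  keys <- unique(df[, c("drug_id", "target_id")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$drug_id == keys$drug_id[i] & df$target_id == keys$target_id[i], ]
    concs <- sort(unique(sub$concentration), decreasing = TRUE)
    reps <- sort(unique(sub$replicate))
    m <- matrix(NA_real_, nrow = length(reps), ncol = length(concs))
    for (j in seq_len(nrow(sub))) {
      m[match(sub$replicate[j], reps), match(sub$concentration[j], concs)] <-
        sub$activity_pct[j]
    }
    dose_response_series(keys$drug_id[i], keys$target_id[i], concs, m, units)
  })
  names(out) <- paste(keys$drug_id, keys$target_id, sep = ":")
  out
}

# 4-parameter logistic on the percent-of-blank scale
logistic4 <- function(conc, bottom, top, ic50, hill) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Default 4PL parameter bounds
#'
#' Bounds on the percent-of-blank scale: bottom in [-10, 50], top in
#' [50, 120], Hill slope in [0.1, 10]; IC50 is bounded to
#' [min(c)/100, max(c)*100] of the observed series at fit time.
#' @return Named list of `c(lower, upper)` bounds.
#' @export
ic50_bounds <- function() {
  list(bottom = c(-10, 50), top = c(50, 120), hill = c(0.1, 10),
       ic50_factor = 100)
}

#' Fit IC50 from a dose-response series
#'
#' Fits `response = bottom + (top - bottom) / (1 + (c / ic50)^hill)` to each
#' replicate independently by nonlinear least squares on log-concentration
#' (bounded L-BFGS-B, initialized from the data midpoint), then reports the
#' mean and sample standard deviation (n-1) of the per-replicate IC50s —
#' the "mean +/- SD" convention of commercial kinase-assay reports. SD is 0
#' for a single replicate. Flat series (response range below `flat_tol`)
#' yield an undefined IC50 with an explicit flag; non-convergence is flagged,
#' never silent.
#'
#' @param series a [dose_response_series()] with >= 4 distinct
#'   concentrations.
#' @param bounds parameter bounds, see [ic50_bounds()].
#' @param flat_tol minimum response range (percentage points) regarded as
#'   signal, default 10.
#' @return Object of class `ic50_fit`: `ic50_mean`, `ic50_sd`, `hill`,
#'   `top`, `bottom` (replicate means), `per_replicate` data frame,
#'   `converged`, `defined`, `rss`, `units`.
#' @export
fit_ic50 <- function(series, bounds = ic50_bounds(), flat_tol = 10) {
  stopifnot(inherits(series, "dose_response_series"))
  concs <- series$concentrations
  if (length(unique(concs)) < 4L) {
    svt_stop("at least 4 distinct concentrations are required for a 4PL fit")
  }
  if (any(!is.finite(series$responses))) {
    svt_stop("responses must be finite")
  }
  ic50_lim <- c(min(concs) / bounds$ic50_factor, max(concs) * bounds$ic50_factor)

  fits <- lapply(seq_len(series$n_replicates), function(r) {
    y <- series$responses[r, ]
    if (diff(range(y)) < flat_tol) {
      return(list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
                  bottom = NA_real_, rss = NA_real_, converged = FALSE,
                  defined = FALSE, extrapolated = NA))
    }
    fit_one_replicate(concs, y, bounds, ic50_lim)
  })
  per_rep <- do.call(rbind, lapply(seq_along(fits), function(r) {
    data.frame(replicate = r, ic50 = fits[[r]]$ic50, hill = fits[[r]]$hill,
               top = fits[[r]]$top, bottom = fits[[r]]$bottom,
               rss = fits[[r]]$rss, converged = fits[[r]]$converged,
               defined = fits[[r]]$defined, extrapolated = fits[[r]]$extrapolated)
  }))
  ok <- per_rep$defined & per_rep$converged
  ic50s <- per_rep$ic50[ok]
  structure(list(
    drug_id = series$drug_id, target_id = series$target_id,
    ic50_mean = if (length(ic50s)) mean(ic50s) else NA_real_,
    ic50_sd = if (length(ic50s) > 1) stats::sd(ic50s) else if (length(ic50s) == 1) 0 else NA_real_,
    hill = if (any(ok)) mean(per_rep$hill[ok]) else NA_real_,
    top = if (any(ok)) mean(per_rep$top[ok]) else NA_real_,
    bottom = if (any(ok)) mean(per_rep$bottom[ok]) else NA_real_,
    per_replicate = per_rep,
    converged = all(per_rep$converged[per_rep$defined]) && any(ok),
    defined = any(per_rep$defined),
    rss = sum(per_rep$rss[ok]),
    units = series$units
  ), class = "ic50_fit")
}

fit_one_replicate <- function(concs, y, bounds, ic50_lim) {
  lx <- log(concs)
  # parameterized as (bottom, top, log ic50, hill); the 4PL on log
  # concentration is a scaled logistic, u = 1/(1 + exp(h (lx - lic))),
  # computed via plogis so extreme exponents never overflow. The analytic
  # gradient keeps the bounded quasi-Newton line search stable and the
  # optimum sharp: E u^2 == u (1 - u).
  obj <- function(par) {
    u <- stats::plogis(-(par[4] * (lx - par[3])))
    sum((y - (par[1] + (par[2] - par[1]) * u))^2)
  }
  grad <- function(par) {
    b <- par[1]; tp <- par[2]; lic <- par[3]; h <- par[4]
    u <- stats::plogis(-(h * (lx - lic)))
    r2 <- 2 * ((b + (tp - b) * u) - y)
    uu <- u * (1 - u)
    c(sum(r2 * (1 - u)),
      sum(r2 * u),
      sum(r2 * (tp - b) * h * uu),
      sum(r2 * (-(tp - b) * (lx - lic) * uu)))
  }
  # midpoint initialization: concentration whose response is nearest to
  # (top0 + bottom0)/2
  top0 <- min(max(max(y), bounds$top[1]), bounds$top[2])
  bot0 <- min(max(min(y), bounds$bottom[1]), bounds$bottom[2])
  mid <- (top0 + bot0) / 2
  lic0 <- lx[which.min(abs(y - mid))]
  lic0 <- min(max(lic0, log(ic50_lim[1])), log(ic50_lim[2]))
  lower <- c(bounds$bottom[1], bounds$top[1], log(ic50_lim[1]), bounds$hill[1])
  upper <- c(bounds$bottom[2], bounds$top[2], log(ic50_lim[2]), bounds$hill[2])
  starts <- list(c(bot0, top0, lic0, 1),
                 c(bot0, top0, lic0, 2),
                 c(bot0, top0, mean(range(lx)), 1))
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, obj, grad, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(factr = 10, pgtol = 1e-10, maxit = 1000)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (!is.null(best)) {
    # polish from the incumbent; a restart also rescues a stalled line search
    res <- tryCatch(
      stats::optim(best$par, obj, grad, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(factr = 10, pgtol = 1e-10, maxit = 1000)),
      error = function(e) NULL)
    if (!is.null(res) && res$value <= best$value) best <- res
  }
  if (is.null(best)) {
    return(list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
                bottom = NA_real_, rss = NA_real_, converged = FALSE,
                defined = TRUE, extrapolated = NA))
  }
  # a line search stalled at machine precision still counts as converged if
  # the bound-projected gradient is (relatively) negligible
  pg <- grad(best$par)
  at_lo <- best$par <= lower + 1e-12
  at_hi <- best$par >= upper - 1e-12
  pg[at_lo & pg > 0] <- 0
  pg[at_hi & pg < 0] <- 0
  converged <- best$convergence == 0L ||
    max(abs(pg)) < 1e-6 * (1 + abs(best$value))
  ic50 <- exp(best$par[3])
  list(ic50 = ic50, hill = best$par[4], top = best$par[2],
       bottom = best$par[1], rss = best$value,
       converged = converged, defined = TRUE,
       extrapolated = ic50 < min(concs) || ic50 > max(concs))
}

#' @export
print.ic50_fit <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("<ic50_fit %s/%s: undefined (no inhibition signal)>\n",
                x$drug_id, x$target_id))
  } else {
    cat(sprintf("<ic50_fit %s/%s: IC50 = %.4g +/- %.4g %s (hill %.2f)%s>\n",
                x$drug_id, x$target_id, x$ic50_mean, x$ic50_sd, x$units,
                x$hill, if (x$converged) "" else " [NOT CONVERGED]"))
  }
  invisible(x)
}

#' Summarize IC50 fits as a report table
#'
#' @param fits list of `ic50_fit` objects.
#' @return data frame mirroring a mean-+/-SD IC50 report: `drug_id`,
#'   `target_id`, `ic50_mean`, `ic50_sd`, `units`, `converged`, `defined`.
#' @export
ic50_table <- function(fits) {
  if (inherits(fits, "ic50_fit")) fits <- list(fits)
  do.call(rbind, lapply(fits, function(f) {
    data.frame(drug_id = f$drug_id, target_id = f$target_id,
               ic50_mean = f$ic50_mean, ic50_sd = f$ic50_sd, units = f$units,
               converged = f$converged, defined = f$defined,
               stringsAsFactors = FALSE)
  }))
}
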