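#' Normalize raw well values to the upper plateau (TOP)
#'
#' Rescales blank-corrected absorbance so that the vehicle-control mean maps
#' to 1 and the blank-corrected zero maps to 0. All dose-response fitting in
#' the pipeline operates on this normalized scale.
#'
#' @param values Numeric vector of raw well values.
#' @param reference Numeric vector of vehicle-control (upper-plateau) well
#'   values on the same raw scale.
#' @param blank Scalar blank level subtracted from both (default 0; pass the
#'   mean of the full-inhibition controls to anchor the assay floor).
#' @return Numeric vector of normalized responses (vehicle mean = 1).
#' @export
normalize_to_top <- function(values, reference, blank = 0) {
  ref <- mean(reference) - blank
  if (!is.finite(ref) || ref <= 0)
    stop("reference mean minus blank is not positive; plate unusable")
  (values - blank) / ref
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Fits `y = bottom + (top - bottom) / (1 + (dose / ec50)^hill)` by
#' Levenberg-Marquardt least squares ([minpack.lm::nlsLM()]). With
#' `hill > 0` the response falls from `top` at low dose to `bottom` at high
#' dose — the inhibition convention used throughout.
#'
#' EC50 is optimized as `log10(ec50)` with box bounds spanning the tested
#' doses plus two decades on either side, initialized from the dose pair
#' bracketing the half-maximal response; this keeps the otherwise
#' ill-conditioned 4PL fit stable. By default `bottom` is constrained to be
#' `>= 0` and `top` is free, matching the normalized assay floor while
#' tolerating overshoot.
#'
#' Absorbance-derived readouts carry noise that scales with the signal, so
#' the default is relative weighting (`weighting = "relative"`): after an
#' unweighted pass the fit is iteratively reweighted with `1 / fitted^2`.
#' `weighting = "none"` gives plain least squares (constant-variance
#' assumption).
#'
#' 95% confidence intervals are asymptotic (curvature-based, t quantile on
#' `n - 4` df; the EC50 interval is computed on the log10 scale and
#' back-transformed). `ci = "bootstrap"` replaces them with percentile
#' intervals from a case bootstrap within dose groups.
#'
#' Non-convergence is always reported, never silent: exactly flat data, an
#' optimizer failure, or an EC50 estimate pinned to its search bound yield
#' `converged = FALSE` with a `reason`.
#'
#' @param doses Numeric vector of doses (molar, > 0).
#' @param responses Numeric vector of responses (same length).
#' @param assay Optional assay label carried into the result.
#' @param lower,upper Named numeric bounds for `top`, `bottom`, `hill`
#'   overriding the defaults (`bottom >= 0`, `0.05 <= hill <= 20`).
#' @param weighting `"relative"` (default, weights `1/fitted^2`) or
#'   `"none"`.
#' @param ci `"asymptotic"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates when `ci = "bootstrap"`.
#' @param boot_seed Integer seed for the bootstrap resampling.
#' @return An object of class `curve_fit`: list with `top`, `bottom`,
#'   `hill`, `ec50`, `log10_ec50`, `ci` (parameter x bound matrix, 95%),
#'   `converged`, `reason`, `n_points`, `assay`, `fitted`, `residuals`,
#'   `doses`, `responses`.
#' @export
fit_4pl <- function(doses, responses, assay = NA_character_,
                    lower = NULL, upper = NULL,
                    weighting = c("relative", "none"),
                    ci = c("asymptotic", "bootstrap"),
                    n_boot = 200L, boot_seed = 1L) {
  ci <- match.arg(ci)
  weighting <- match.arg(weighting)
  if (length(doses) != length(responses))
    stop("doses and responses must have equal length")
  keep <- is.finite(doses) & is.finite(responses) & doses > 0
  doses <- doses[keep]; responses <- responses[keep]
  n <- length(doses)
  if (length(unique(doses)) < 4L)
    stop("need at least 4 distinct positive doses")

  fail <- function(reason) {
    structure(list(top = NA_real_, bottom = NA_real_, hill = NA_real_,
                   ec50 = NA_real_, log10_ec50 = NA_real_, ci = NULL,
                   converged = FALSE, reason = reason, n_points = n,
                   assay = assay, fitted = NULL, residuals = NULL,
                   doses = doses, responses = responses),
              class = "curve_fit")
  }
  u_dose <- sort(unique(doses))
  dose_means <- vapply(u_dose, function(d) mean(responses[doses == d]),
                       numeric(1))
  if (diff(range(dose_means)) == 0)
    return(fail("flat data: response does not vary with dose"))

  ld <- log10(doses)
  lo <- c(top = -Inf, bottom = 0, hill = 0.05, le = min(ld) - 2)
  hi <- c(top = Inf, bottom = Inf, hill = 20, le = max(ld) + 2)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper

  ud <- log10(u_dose)
  top0 <- dose_means[1]
  bot0 <- dose_means[length(dose_means)]
  half <- (top0 + bot0) / 2
  le0 <- ud[which.min(abs(dose_means - half))]
  start <- c(top = max(top0, bot0), bottom = max(min(top0, bot0), lo["bottom"]),
             hill = 1, le = le0)
  start <- pmin(pmax(start, lo + 1e-9), hi - 1e-9)
  names(start) <- c("top", "bottom", "hill", "le")

  do_fit <- function(st, w = NULL) {
    args <- list(
      responses ~ bottom + (top - bottom) / (1 + 10^(hill * (ld - le))),
      start = as.list(st), lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!is.null(w)) args$weights <- w
    tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) NULL)
  }
  # fallback starts guard against rank-deficient Jacobians at the first guess
  starts <- list(start,
                 start + c(0, 0, 0.2, 0.25),
                 start * c(1.05, 0.5, 0.8, 1) - c(0, 0, 0, 0.25))
  fit <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lo + 1e-9), hi - 1e-9)
    fit <- do_fit(st)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(fail("optimizer failed"))
  if (weighting == "relative") {
    for (it in 1:3) {
      fv <- abs(stats::fitted(fit))
      w <- 1 / pmax(fv, 0.05 * max(fv))^2
      refit <- do_fit(stats::coef(fit), w)
      if (is.null(refit)) break
      fit <- refit
    }
  }
  cf <- stats::coef(fit)
  if (cf["le"] <= lo["le"] + 1e-6 || cf["le"] >= hi["le"] - 1e-6)
    return(fail("EC50 estimate pinned to search bound; curve unidentified"))

  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, 4) else sqrt(pmax(diag(vc), 0))
  tq <- stats::qt(0.975, df = max(n - 4L, 1L))
  ci_mat <- cbind(low = cf - tq * se, high = cf + tq * se)
  if (ci == "bootstrap") {
    ci_mat <- boot_ci_4pl(doses, responses, lo, hi, cf, n_boot, boot_seed)
  }
  # back-transform the log10(ec50) row
  ec_row <- 10^ci_mat["le", ]
  ci_out <- rbind(ci_mat[c("top", "bottom", "hill"), , drop = FALSE],
                  ec50 = ec_row)

  structure(list(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
                 hill = unname(cf["hill"]), ec50 = unname(10^cf["le"]),
                 log10_ec50 = unname(cf["le"]), ci = ci_out,
                 converged = TRUE, reason = NA_character_, n_points = n,
                 assay = assay, fitted = stats::fitted(fit),
                 residuals = stats::resid(fit),
                 doses = doses, responses = responses),
            class = "curve_fit")
}

boot_ci_4pl <- function(doses, responses, lo, hi, cf, n_boot, boot_seed) {
  ld <- log10(doses)
  groups <- split(seq_along(doses), doses)
  draws <- withr::with_seed(boot_seed, {
    replicate(n_boot, {
      idx <- unlist(lapply(groups, function(g)
        g[sample.int(length(g), length(g), replace = TRUE)]))
      d <- doses[idx]; y <- responses[idx]; l <- log10(d)
      f <- tryCatch(
        minpack.lm::nlsLM(
          y ~ bottom + (top - bottom) / (1 + 10^(hill * (l - le))),
          start = as.list(cf), lower = lo, upper = hi,
          control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
      if (is.null(f)) rep(NA_real_, 4) else stats::coef(f)
    })
  })
  t(apply(draws, 1, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE,
          names = FALSE)) -> q
  dimnames(q) <- list(names(cf), c("low", "high"))
  q
}

#' @export
print.curve_fit <- function(x, ...) {
  if (!x$converged) {
    cat("4PL fit (", x$n_points, " points): NOT converged - ", x$reason,
        "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "4PL fit (%d points%s): top=%.4g bottom=%.4g hill=%.3g EC50=%.4g M",
    x$n_points, if (is.na(x$assay)) "" else paste0(", ", x$assay),
    x$top, x$bottom, x$hill, x$ec50), "\n")
  if (!is.null(x$ci))
    cat(sprintf("  EC50 95%% CI: [%.4g, %.4g] M\n",
                x$ci["ec50", "low"], x$ci["ec50", "high"]))
  invisible(x)
}

#' Effective concentration at an arbitrary effect level
#'
#' Closed form `EC_f = EC50 * (f / (100 - f))^(1 / hill)` for the dose
#' producing `f` percent of the maximal effect between the fitted plateaus
#' (the relative definition; `ec_f(fit, 50)` is exactly the fitted EC50).
#' With `relative = FALSE`, `f` is instead read as percent inhibition on the
#' normalized 0-1 response scale and the dose is found by inverting the
#' fitted curve at `y = 1 - f/100`, which must lie strictly between the
#' fitted plateaus.
#'
#' @param fit A converged `curve_fit`.
#' @param f Effect level in percent, strictly between 0 and 100.
#' @param relative Use the relative (between-plateau) definition (default).
#' @return Dose in molar.
#' @export
ec_f <- function(fit, f, relative = TRUE) {
  stopifnot(inherits(fit, "curve_fit"))
  if (!fit$converged) stop("fit did not converge; EC_f undefined")
  if (any(f <= 0 | f >= 100)) stop("f must lie strictly between 0 and 100")
  if (relative) {
    fit$ec50 * (f / (100 - f))^(1 / fit$hill)
  } else {
    y <- 1 - f / 100
    loy <- min(fit$top, fit$bottom); hiy <- max(fit$top, fit$bottom)
    if (any(y <= loy | y >= hiy))
      stop("absolute effect level outside the fitted response range")
    fit$ec50 * ((fit$top - y) / (y - fit$bottom))^(1 / fit$hill)
  }
}

#' Working dose from a fitted EC50
#'
#' The follow-up dosing rule: a fixed multiple of the fitted EC50
#' (default 10x).
#'
#' @param fit A converged `curve_fit`.
#' @param factor Multiple of EC50 (default 10).
#' @return Dose in molar.
#' @export
working_dose <- function(fit, factor = 10) {
  stopifnot(inherits(fit, "curve_fit"))
  if (!fit$converged) stop("fit did not converge")
  factor * fit$ec50
}

#' Therapeutic index with censoring at the highest tested dose
#'
#' `T.i. = IC50(toxicity) / EC50(efficacy)`. When the toxicity curve did not
#' converge (no toxicity response in the tested range) or its IC50 exceeds
#' the highest tested concentration, the index is censored: the reported
#' ratio `max_tested / EC50` is a lower bound on the true index.
#'
#' @param effective Converged `curve_fit` of the efficacy endpoint.
#' @param toxic `curve_fit` of the toxicity endpoint (may be unconverged).
#' @param max_tested Highest tested toxicity concentration (molar).
#' @return list of class `therapeutic_index`: `ratio`, `censored`,
#'   `toxicity_endpoint`.
#' @export
therapeutic_index <- function(effective, toxic, max_tested) {
  stopifnot(inherits(effective, "curve_fit"), inherits(toxic, "curve_fit"))
  if (!effective$converged)
    stop("effective fit did not converge; therapeutic index undefined")
  if (!is.finite(max_tested) || max_tested <= 0)
    stop("max_tested must be a positive dose")
  censored <- !toxic$converged || toxic$ec50 > max_tested
  ratio <- if (censored) max_tested / effective$ec50
           else toxic$ec50 / effective$ec50
  structure(list(ratio = ratio, censored = censored,
                 toxicity_endpoint = toxic$assay),
            class = "therapeutic_index")
}

#' @export
print.therapeutic_index <- function(x, ...) {
  cat(sprintf("Therapeutic index%s: %s%.3g%s\n",
              if (is.na(x$toxicity_endpoint)) "" else
                paste0(" (", x$toxicity_endpoint, ")"),
              if (x$censored) "> " else "", x$ratio,
              if (x$censored) " (lower bound: IC50 above tested range)" else ""))
  invisible(x)
}

#' Cross-assay EC50 concordance
#'
#' Mean and SD of paired `log10(EC50_a) - log10(EC50_b)` across compounds
#' measured in both assays. Compounds present in only one vector are
#' excluded with a warning.
#'
#' @param ec50_a,ec50_b Named numeric vectors of EC50s (molar), names are
#'   compound ids.
#' @return list with `mean`, `sd`, `n_pairs`.
#' @export
assay_concordance <- function(ec50_a, ec50_b) {
  if (is.null(names(ec50_a)) || is.null(names(ec50_b)))
    stop("EC50 vectors must be named by compound id")
  if (any(ec50_a <= 0, na.rm = TRUE) || any(ec50_b <= 0, na.rm = TRUE))
    stop("EC50s must be positive")
  shared <- intersect(names(ec50_a), names(ec50_b))
  dropped <- setdiff(union(names(ec50_a), names(ec50_b)), shared)
  if (length(dropped))
    warning("excluding unpaired compounds: ", paste(dropped, collapse = ", "))
  if (length(shared) == 0L) stop("no paired compounds")
  d <- log10(ec50_a[shared]) - log10(ec50_b[shared])
  list(mean = mean(d), sd = if (length(d) > 1L) stats::sd(d) else 0,
       n_pairs = length(d))
}

#' Normalize and fit every compound of a screen table
#'
#' For each plate: responses are normalized with the full-inhibition
#' control mean as blank and the vehicle-control wells as reference
#' ([normalize_to_top()]), then one 4PL curve is fitted per compound
#' present on the plate.
#'
#' @param plate_tab Long plate table (`plate_id`, `role`, `compound_id`,
#'   `dose_molar`, `value`), as produced by [generate_screen()].
#' @param assay Assay label stamped on the fits.
#' @param max_role,min_role Plate-map roles of the vehicle (high-signal) and
#'   full-inhibition (low-signal) controls.
#' @param ... Passed on to [fit_4pl()].
#' @return Named list of `curve_fit` objects, one per compound.
#' @export
fit_screen <- function(plate_tab, assay = NA_character_,
                       max_role = "negative-control",
                       min_role = "positive-control", ...) {
  stopifnot(all(c("plate_id", "role", "compound_id", "dose_molar", "value")
                %in% names(plate_tab)))
  fits <- list()
  for (id in unique(plate_tab$plate_id)) {
    pl <- plate_tab[plate_tab$plate_id == id, ]
    blank <- mean(pl$value[pl$role == min_role])
    ref <- pl$value[pl$role == max_role]
    cmp <- pl[pl$role == "compound", ]
    norm <- normalize_to_top(cmp$value, ref, blank = blank)
    for (cid in unique(cmp$compound_id)) {
      sel <- cmp$compound_id == cid
      fits[[cid]] <- fit_4pl(cmp$dose_molar[sel], norm[sel],
                             assay = assay, ...)
    }
  }
  fits
}

#' Tabulate a list of curve fits
#'
#' @param fits Named list of `curve_fit` objects (names are compound ids).
#' @return data.frame: `compound_id`, `assay`, `top`, `bottom`, `hill`,
#'   `ec50_molar`, `ec50_ci_low`, `ec50_ci_high`, `ec5`, `ec95`,
#'   `converged`.
#' @export
fit_table <- function(fits) {
  do.call(rbind, lapply(names(fits), function(cid) {
    f <- fits[[cid]]
    data.frame(
      compound_id = cid, assay = f$assay, top = f$top, bottom = f$bottom,
      hill = f$hill, ec50_molar = f$ec50,
      ec50_ci_low = if (f$converged) f$ci["ec50", "low"] else NA_real_,
      ec50_ci_high = if (f$converged) f$ci["ec50", "high"] else NA_real_,
      ec5 = if (f$converged) ec_f(f, 5) else NA_real_,
      ec95 = if (f$converged) ec_f(f, 95) else NA_real_,
      converged = f$converged, stringsAsFactors = FALSE)
  }))
}
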