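#' Plate quality-control metrics from control wells
#'
#' Computes the four standard screening quality statistics from the two
#' control populations of a plate: Z-prime, signal window (SW),
#' signal-to-background (S:B) and signal-to-noise (S:N).
#'
#' `pos` is the high-signal control group and `neg` the low-signal group;
#' which plate-map role carries the high signal is declared by the caller
#' (in an anti-proliferative screen the vehicle wells are the high signal),
#' never inferred from the data.
#'
#' Definitions, with `mu`/`sigma` the group means and sample SDs and `n`
#' the wells per group:
#' \itemize{
#'   \item `Z' = 1 - 3 (sigma_pos + sigma_neg) / |mu_pos - mu_neg|`
#'   \item `SW = (|mu_pos - mu_neg| - 3 (sigma_pos/sqrt(n_pos) +
#'          sigma_neg/sqrt(n_neg))) / (sigma_pos / sqrt(n_pos))`
#'          (replicate-adjusted form; `sw_replicate_adjusted = FALSE` drops
#'          the `sqrt(n)` terms)
#'   \item `S:B = mu_pos / mu_neg`
#'   \item `S:N = (mu_pos - mu_neg) / sigma_neg`
#' }
#'
#' @param pos Numeric vector of high-signal control well values (>= 2).
#' @param neg Numeric vector of low-signal control well values (>= 2).
#' @param plate_id Optional plate identifier carried into the result.
#' @param sw_replicate_adjusted Use the replicate-adjusted SW definition
#'   (default `TRUE`).
#' @return An object of class `plate_qc`: a one-row data.frame with
#'   `plate_id`, `zprime`, `sw`, `sb`, `sn`, `n_pos`, `n_neg`, `usable`.
#'   Plates with equal control means are flagged `usable = FALSE` with all
#'   metrics `NA`.
#' @export
plate_metrics <- function(pos, neg, plate_id = NA_character_,
                          sw_replicate_adjusted = TRUE) {
  if (length(pos) < 2L || length(neg) < 2L)
    stop("need at least 2 wells per control group")
  if (anyNA(pos) || anyNA(neg)) stop("control wells contain NA")
  mu_p <- mean(pos); mu_n <- mean(neg)
  sd_p <- stats::sd(pos); sd_n <- stats::sd(neg)
  n_p <- length(pos); n_n <- length(neg)
  if (mu_p == mu_n) {
    out <- data.frame(plate_id = plate_id, zprime = NA_real_, sw = NA_real_,
                      sb = NA_real_, sn = NA_real_, n_pos = n_p, n_neg = n_n,
                      usable = FALSE, stringsAsFactors = FALSE)
    class(out) <- c("plate_qc", class(out))
    return(out)
  }
  sep <- abs(mu_p - mu_n)
  zprime <- 1 - 3 * (sd_p + sd_n) / sep
  if (sw_replicate_adjusted) {
    sw <- (sep - 3 * (sd_p / sqrt(n_p) + sd_n / sqrt(n_n))) /
      (sd_p / sqrt(n_p))
  } else {
    sw <- (sep - 3 * (sd_p + sd_n)) / sd_p
  }
  out <- data.frame(plate_id = plate_id, zprime = zprime, sw = sw,
                    sb = mu_p / mu_n, sn = (mu_p - mu_n) / sd_n,
                    n_pos = n_p, n_neg = n_n, usable = TRUE,
                    stringsAsFactors = FALSE)
  class(out) <- c("plate_qc", class(out))
  out
}

#' QC metrics for every plate of a screen table
#'
#' Convenience wrapper applying [plate_metrics()] per plate of a long-format
#' plate table (as produced by [generate_screen()] or read from a plate CSV).
#'
#' @param plate_tab data.frame with at least `plate_id`, `role`, `value`.
#' @param max_role Plate-map role carrying the high signal (default
#'   `"negative-control"`: vehicle wells in an anti-proliferative readout).
#' @param min_role Role carrying the low signal.
#' @inheritParams plate_metrics
#' @return data.frame with one row per plate (rbind of `plate_qc` rows).
#' @export
screen_qc <- function(plate_tab, max_role = "negative-control",
                      min_role = "positive-control",
                      sw_replicate_adjusted = TRUE) {
  stopifnot(all(c("plate_id", "role", "value") %in% names(plate_tab)))
  ids <- unique(plate_tab$plate_id)
  do.call(rbind, lapply(ids, function(id) {
    pl <- plate_tab[plate_tab$plate_id == id, ]
    plate_metrics(pl$value[pl$role == max_role],
                  pl$value[pl$role == min_role],
                  plate_id = id,
                  sw_replicate_adjusted = sw_replicate_adjusted)
  }))
}

#' Plate- and screen-level acceptance decisions
#'
#' A plate is rejected when `Z' < zprime_min` or `SW < sw_min` (strict
#' inequalities: a plate at exactly `Z' = 0.3` is retained). The screen as a
#' whole is accepted when the mean Z-prime over the retained plates is at
#' least `zprime_screen` and the mean SW at least `sw_screen`. Rejected
#' plates are excluded from the screen-level averages.
#'
#' @param qc data.frame of plate QC rows (from [screen_qc()] or rbind of
#'   [plate_metrics()] results).
#' @param zprime_min,sw_min Plate rejection thresholds (defaults 0.3, 1).
#' @param zprime_screen,sw_screen Screen acceptance thresholds on retained-
#'   plate averages (defaults 0.5, 2).
#' @return list with `plates` (input plus `plate_accepted`), `screen_accepted`,
#'   `mean_zprime`, `mean_sw`, `n_retained`, and `reason` when rejected.
#' @export
screen_acceptance <- function(qc, zprime_min = 0.3, sw_min = 1,
                              zprime_screen = 0.5, sw_screen = 2) {
  if (nrow(qc) < 1L) stop("need at least one plate")
  ok <- qc$usable & qc$zprime >= zprime_min & qc$sw >= sw_min
  ok[is.na(ok)] <- FALSE
  qc$plate_accepted <- ok
  if (!any(ok)) {
    return(list(plates = qc, screen_accepted = FALSE,
                mean_zprime = NA_real_, mean_sw = NA_real_, n_retained = 0L,
                reason = "all plates rejected"))
  }
  mz <- mean(qc$zprime[ok]); ms <- mean(qc$sw[ok])
  accepted <- mz >= zprime_screen && ms >= sw_screen
  list(plates = qc, screen_accepted = accepted,
       mean_zprime = mz, mean_sw = ms, n_retained = sum(ok),
       reason = if (accepted) NA_character_ else
         "retained-plate averages below screen thresholds")
}

#' Compound activity call from repeated dose-response fits
#'
#' A compound is called active when it was measured in at least `min_reps`
#' biological repetitions and its summary EC50 — the geometric mean over
#' repetitions — is below `threshold` in both the primary (BrdU) and the
#' validation (WST-1) assay.
#'
#' @param fits data.frame with columns `compound_id`, `assay`, `repetition`,
#'   `ec50` (molar) — one row per converged fit.
#' @param compound_id Compound to call.
#' @param assays Character vector of the two required assay labels.
#' @param threshold Activity threshold on EC50 in molar (default `1e-5`,
#'   i.e. 10 uM).
#' @param min_reps Minimum biological repetitions (default 3).
#' @return One-row data.frame: `compound_id`, `n_repetitions`, `ec50_brdu`,
#'   `ec50_wst`, `active`, `reason`. Summary EC50s are geometric means; a
#'   missing assay yields `active = FALSE` with reason
#'   "insufficient evidence".
#' @export
call_active <- function(fits, compound_id,
                        assays = c("BrdU", "WST-1"),
                        threshold = 1e-5, min_reps = 3L) {
  stopifnot(all(c("compound_id", "assay", "repetition", "ec50") %in%
                  names(fits)))
  f <- fits[fits$compound_id == compound_id & fits$assay %in% assays, ]
  gm <- function(x) exp(mean(log(x)))
  e1 <- f$ec50[f$assay == assays[1]]
  e2 <- f$ec50[f$assay == assays[2]]
  n_rep <- length(unique(f$repetition))
  if (length(e1) == 0L || length(e2) == 0L) {
    return(data.frame(compound_id = compound_id, n_repetitions = n_rep,
                      ec50_brdu = if (length(e1)) gm(e1) else NA_real_,
                      ec50_wst = if (length(e2)) gm(e2) else NA_real_,
                      active = FALSE, reason = "insufficient evidence",
                      stringsAsFactors = FALSE))
  }
  g1 <- gm(e1); g2 <- gm(e2)
  active <- n_rep >= min_reps && g1 < threshold && g2 < threshold
  reason <- if (active) NA_character_
    else if (n_rep < min_reps) "fewer than required repetitions"
    else "summary EC50 at or above threshold in at least one assay"
  data.frame(compound_id = compound_id, n_repetitions = n_rep,
             ec50_brdu = g1, ec50_wst = g2, active = active,
             reason = reason, stringsAsFactors = FALSE)
}
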