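#' Benjamini-Hochberg adjustment with rejection set
#'
#' Step-up linear FDR adjustment. Thin wrapper around [stats::p.adjust()]
#' returning the adjusted values together with the rejection set at `q`.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\]. `NA` entries are
#'   excluded from the procedure and reported back as `NA` with
#'   `discovery = FALSE`.
#' @param q Target FDR level in (0, 1).
#' @return A data.frame with columns `p`, `q_value` (BH adjusted) and
#'   `discovery` (`q_value <= q`). Row order matches the input.
#' @export
bh_adjust <- function(p, q = 0.05) {
  check_pvalues(p, q)
  qv <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  qv[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(p = p, q_value = qv,
             discovery = !is.na(qv) & qv <= q)
}

#' Benjamini-Yekutieli adjustment
#'
#' BH step-up with the harmonic-sum inflation factor `sum(1/i)`, valid under
#' arbitrary dependence. Adjusted values dominate BH elementwise.
#'
#' @inheritParams bh_adjust
#' @return A data.frame with columns `p`, `q_value` (BY adjusted) and
#'   `discovery`.
#' @export
by_adjust <- function(p, q = 0.05) {
  check_pvalues(p, q)
  qv <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  qv[ok] <- stats::p.adjust(p[ok], method = "BY")
  data.frame(p = p, q_value = qv,
             discovery = !is.na(qv) & qv <= q)
}

#' Two-stage adaptive FDR control (Benjamini-Krieger-Yekutieli)
#'
#' The two-stage step-up procedure: stage 1 runs BH at the shrunk level
#' `q' = q / (1 + q)` and uses its rejection count `r1` to estimate the
#' number of true nulls `m0 = m - r1`; stage 2 reruns BH at level
#' `q' * m / m0`. The adaptive second stage recovers power lost to a large
#' non-null fraction while keeping FDR <= q.
#'
#' Discovery flags follow the stage-2 step-up exactly: when stage 1 rejects
#' nothing the procedure stops with zero discoveries, and when `m0 = 0`
#' (stage 1 rejected everything) all hypotheses are rejected.
#'
#' @inheritParams bh_adjust
#' @param q Target FDR level in (0, 1).
#' @return A list with `discovery` (logical vector in input order),
#'   `q_value` (adaptive adjusted values: BH adjusted scaled by `m0/m`,
#'   capped at 1), `stage1_rejections`, `m0`, `stage2_level` and `m`
#'   (number of non-missing p-values).
#' @export
bky_two_stage <- function(p, q = 0.01) {
  check_pvalues(p, q)
  ok <- !is.na(p)
  m <- sum(ok)
  disc <- rep(FALSE, length(p))
  qv <- rep(NA_real_, length(p))
  if (m == 0L) {
    return(list(discovery = disc, q_value = qv, stage1_rejections = 0L,
                m0 = 0L, stage2_level = NA_real_, m = 0L))
  }
  pp <- p[ok]
  q1 <- q / (1 + q)
  bh <- stats::p.adjust(pp, method = "BH")
  r1 <- sum(bh <= q1)
  m0 <- m - r1
  if (r1 == 0L) {
    d <- rep(FALSE, m)
    lvl <- q1
    qv_ok <- bh             # m0 = m, scaling is identity
  } else if (m0 == 0L) {
    d <- rep(TRUE, m)
    lvl <- Inf
    qv_ok <- rep(0, m)
  } else {
    lvl <- q1 * m / m0
    d <- bh <= lvl
    qv_ok <- pmin(1, bh * m0 / m)
  }
  disc[ok] <- d
  qv[ok] <- qv_ok
  list(discovery = disc, q_value = qv, stage1_rejections = r1,
       m0 = m0, stage2_level = lvl, m = m)
}

check_pvalues <- function(p, q) {
  if (!is.numeric(p)) stop("p must be a numeric vector")
  bad <- !is.na(p) & (p < 0 | p > 1 | !is.finite(p))
  if (any(bad)) stop("p-values must be finite and within [0, 1]")
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q >= 1)
    stop("q must be a single number in (0, 1)")
  invisible(TRUE)
}

#' Row-wise unpaired two-sample t-tests
#'
#' Vectorized per-feature two-sample t-test between two column groups of a
#' numeric matrix. Pooled variance by default (the convention of the usual
#' multiple-t-test workflow in screening software); Welch behind a flag.
#'
#' Features with zero variance in both groups get `p = 1` when the group
#' means are equal; when the means differ an epsilon variance floor
#' (`var_floor`) keeps the statistic finite and the feature is flagged in
#' the `degenerate` column.
#'
#' @param x Numeric matrix, features in rows, samples in columns.
#' @param idx1,idx2 Column indices (or logical masks) of the two groups;
#'   each group needs >= 2 columns.
#' @param var_equal Pooled-variance test if `TRUE` (default), Welch
#'   otherwise.
#' @param var_floor Minimum allowed pooled variance; only engaged when the
#'   empirical variance is exactly zero.
#' @return data.frame with `mean1`, `mean2`, `diff` (`mean1 - mean2`),
#'   `t`, `df`, `p`, `degenerate`.
#' @export
row_t_test <- function(x, idx1, idx2, var_equal = TRUE, var_floor = 1e-12) {
  x <- as.matrix(x)
  x1 <- x[, idx1, drop = FALSE]
  x2 <- x[, idx2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    degen <- sp2 <= 0
    sp2 <- pmax(sp2, var_floor)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(x))
  } else {
    degen <- v1 + v2 <= 0
    v1f <- pmax(v1, var_floor); v2f <- pmax(v2, var_floor)
    se <- sqrt(v1f / n1 + v2f / n2)
    df <- (v1f / n1 + v2f / n2)^2 /
      ((v1f / n1)^2 / (n1 - 1) + (v2f / n2)^2 / (n2 - 1))
  }
  tt <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tt), df)
  p[degen & m1 == m2] <- 1
  data.frame(mean1 = m1, mean2 = m2, diff = m1 - m2,
             t = tt, df = df, p = p, degenerate = degen,
             row.names = rownames(x))
}

#' Adjust a p-value table file
#'
#' File-level convenience over the adjustment procedures: reads a TSV with a
#' `feature_id` and `p` column, appends `q` and `discovery`, and writes the
#' result back (or to `out`).
#'
#' @param path Input TSV path with columns `feature_id`, `p`.
#' @param method One of "BH", "BY", "BKY".
#' @param q Target FDR level.
#' @param out Output path; defaults to overwriting `path`.
#' @return The augmented data.frame, invisibly.
#' @export
adjust_pvalue_file <- function(path, method = c("BKY", "BH", "BY"),
                               q = 0.05, out = path) {
  method <- match.arg(method)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("feature_id", "p") %in% names(tab)))
    stop("input must have columns feature_id and p")
  res <- switch(method,
    BH  = bh_adjust(tab$p, q),
    BY  = by_adjust(tab$p, q),
    BKY = {
      r <- bky_two_stage(tab$p, q)
      data.frame(q_value = r$q_value, discovery = r$discovery)
    })
  tab$q <- res$q_value
  tab$discovery <- res$discovery
  utils::write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
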