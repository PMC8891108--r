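#' Reference-gene (housekeeping) normalization of panel counts
#'
#' Per-sample scale factor = geometric mean of the reference-gene counts in
#' that sample, divided by the across-sample mean of those geometric means;
#' counts are divided by the factor. After normalization the reference-gene
#' geometric means are equal across samples. A reference gene with a zero
#' count in any sample is excluded from the factor computation with a
#' warning (at least 2 usable reference genes must remain).
#'
#' @param counts Numeric matrix (genes x samples), non-negative.
#' @param reference_genes Character vector of reference gene ids (rownames
#'   of `counts`).
#' @return list with `normalized` (matrix), `factors` (per-sample),
#'   `used_reference_genes`.
#' @export
normalize_reference_genes <- function(counts, reference_genes) {
  counts <- as.matrix(counts)
  missing <- setdiff(reference_genes, rownames(counts))
  if (length(missing))
    stop("reference genes absent from matrix: ",
         paste(missing, collapse = ", "))
  ref <- counts[reference_genes, , drop = FALSE]
  zero <- rowSums(ref == 0) > 0
  if (any(zero)) {
    warning("excluding reference gene(s) with zero counts: ",
            paste(reference_genes[zero], collapse = ", "))
    ref <- ref[!zero, , drop = FALSE]
  }
  if (nrow(ref) < 2L)
    stop("fewer than 2 usable reference genes")
  geo <- exp(colMeans(log(ref)))
  factors <- geo / mean(geo)
  list(normalized = sweep(counts, 2, factors, "/"),
       factors = factors,
       used_reference_genes = rownames(ref))
}

#' Call differentially expressed genes with an FDR and fold-change gate
#'
#' Per-gene two-sample test on `log2(normalized + pseudocount)` between a
#' treatment and control, with optional per-donor centering to absorb
#' donor/lot batch effects (each donor's samples are centered on that
#' donor's mean before testing). A gene is a DEG only when both gates hold:
#' adjusted `q <= q_level` (two-stage adaptive FDR by default) and
#' `|log2FC| >= min_abs_log2fc`. Both criteria are recorded separately.
#'
#' Genes with zero counts in every sample of both groups are excluded from
#' testing and reported in `excluded`.
#'
#' @param normalized Normalized count matrix (genes x samples).
#' @param treatment Per-sample treatment labels.
#' @param treat,control Compared labels.
#' @param donor Per-sample donor/lot labels for blocking, or `NULL` for the
#'   unblocked test.
#' @param q_level FDR level (default 0.05).
#' @param min_abs_log2fc Fold-change gate in log2 units (default 1).
#' @param adjust `"BKY"` (default) or `"BY"`.
#' @param pseudocount Added before the log transform (default 0.5).
#' @return list with `table` (per-gene `feature_id`, `log2_fc`, `p`,
#'   `q_value`, `significant`, `large_effect`, `discovery`, `direction`)
#'   and `excluded` (all-zero genes).
#' @export
call_degs <- function(normalized, treatment, treat, control,
                      donor = NULL, q_level = 0.05, min_abs_log2fc = 1,
                      adjust = c("BKY", "BY"), pseudocount = 0.5) {
  adjust <- match.arg(adjust)
  m <- as.matrix(normalized)
  sel <- treatment %in% c(treat, control)
  m <- m[, sel, drop = FALSE]
  grp <- treatment[sel]
  if (!is.null(donor)) donor <- donor[sel]
  if (length(unique(grp)) != 2L) stop("treat and control must both be present")
  allzero <- rowSums(m) == 0
  excluded <- rownames(m)[allzero]
  m <- m[!allzero, , drop = FALSE]
  lg <- log2(m + pseudocount)
  i_t <- which(grp == treat); i_c <- which(grp == control)
  if (length(i_t) < 2L || length(i_c) < 2L)
    stop("need >= 2 samples per group")
  log2_fc <- rowMeans(lg[, i_t, drop = FALSE]) -
    rowMeans(lg[, i_c, drop = FALSE])
  test_mat <- lg
  if (!is.null(donor)) {
    if (length(unique(donor)) < 2L) stop("blocking needs >= 2 donors")
    for (d in unique(donor)) {
      cols <- donor == d
      test_mat[, cols] <- lg[, cols, drop = FALSE] -
        rowMeans(lg[, cols, drop = FALSE])
    }
  }
  tt <- row_t_test(test_mat, i_t, i_c)
  adj <- if (adjust == "BKY") bky_two_stage(tt$p, q_level) else
    by_adjust(tt$p, q_level)
  qv <- adj$q_value
  sig <- adj$discovery
  large <- abs(log2_fc) >= min_abs_log2fc
  tab <- data.frame(
    feature_id = rownames(m), log2_fc = log2_fc, p = tt$p, q_value = qv,
    significant = sig, large_effect = large,
    discovery = sig & large,
    direction = ifelse(log2_fc >= 0, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(tab, "treatment") <- treat
  list(table = tab, excluded = excluded)
}

#' Shared DEG sets across treatments
#'
#' Classifies genes by the consistency of their DEG calls across several
#' per-treatment discovery tables: the "all" set contains genes that are
#' DEGs with the same direction in every table; the "near" set contains
#' genes that are same-direction DEGs in at least `min_conditions` (but not
#' all) tables. Genes called up in one treatment and down in another are
#' direction conflicts and belong to neither set.
#'
#' @param tables Named list (>= 2) of DEG tables (the `table` element of
#'   [call_degs()], or any data.frame with `feature_id`, `discovery`,
#'   `direction`).
#' @param min_conditions Minimum same-direction calls for the "near" set.
#' @return list with `all` and `near` data.frames (`feature_id`,
#'   `direction`, `n_conditions`) and `conflicts` (character vector).
#' @export
shared_deg_sets <- function(tables, min_conditions = length(tables) - 1L) {
  if (length(tables) < 2L) stop("need >= 2 treatment tables")
  n_tab <- length(tables)
  hits <- do.call(rbind, lapply(tables, function(t)
    t[t$discovery, c("feature_id", "direction"), drop = FALSE]))
  if (is.null(hits) || nrow(hits) == 0L)
    return(list(all = empty_set(), near = empty_set(),
                conflicts = character()))
  feats <- unique(hits$feature_id)
  up <- table(factor(hits$feature_id[hits$direction == "up"], levels = feats))
  dn <- table(factor(hits$feature_id[hits$direction == "down"],
                     levels = feats))
  conflict <- feats[up > 0 & dn > 0]
  clean <- setdiff(feats, conflict)
  n <- as.integer(up[clean] + dn[clean])
  dir <- ifelse(up[clean] > 0, "up", "down")
  all_set <- data.frame(feature_id = clean[n == n_tab],
                        direction = dir[n == n_tab],
                        n_conditions = n[n == n_tab],
                        stringsAsFactors = FALSE, row.names = NULL)
  near_sel <- n >= min_conditions & n < n_tab
  near_set <- data.frame(feature_id = clean[near_sel],
                         direction = dir[near_sel],
                         n_conditions = n[near_sel],
                         stringsAsFactors = FALSE, row.names = NULL)
  list(all = all_set, near = near_set, conflicts = conflict)
}

empty_set <- function()
  data.frame(feature_id = character(), direction = character(),
             n_conditions = integer(), stringsAsFactors = FALSE)

#' Pathway signature scores
#'
#' Scores each pathway per condition as the mean expression of its member
#' genes (mean over genes of the gene's mean expression across the
#' condition's samples), then centers each signature on its across-condition
#' mean, so normalized scores sum to zero across conditions for every
#' pathway.
#'
#' @param expr Expression matrix (genes x samples), typically log2
#'   normalized counts.
#' @param gene_sets Named list of character vectors (pathway -> gene ids),
#'   e.g. from [read_gmt()].
#' @param condition Per-sample condition labels.
#' @return data.frame: `pathway`, `condition`, `score`,
#'   `normalized_score`. Pathways with no measured member genes are skipped
#'   with a message.
#' @export
pathway_signature_scores <- function(expr, gene_sets, condition) {
  expr <- as.matrix(expr)
  conds <- unique(condition)
  cond_means <- vapply(conds, function(cn)
    rowMeans(expr[, condition == cn, drop = FALSE]), numeric(nrow(expr)))
  out <- list()
  for (pw in names(gene_sets)) {
    genes <- intersect(gene_sets[[pw]], rownames(expr))
    if (length(genes) == 0L) {
      message("pathway '", pw, "' has no measured genes; skipped")
      next
    }
    sc <- colMeans(cond_means[genes, , drop = FALSE])
    out[[pw]] <- data.frame(pathway = pw, condition = conds,
                            score = sc, normalized_score = sc - mean(sc),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  if (length(out) == 0L)
    return(data.frame(pathway = character(), condition = character(),
                      score = numeric(), normalized_score = numeric()))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (tab-separated: set name, description, gene ids).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(x) x[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  sets
}

#' Filter low-expressed genes by counts-per-million
#'
#' A gene is retained when its CPM exceeds `min_cpm` in at least
#' `min_samples` samples (strict inequality on CPM; `>=` on the sample
#' count). Library sizes are the column sums unless supplied.
#'
#' @param counts Count matrix (genes x samples).
#' @param min_cpm CPM threshold (default 0.25).
#' @param min_samples Minimum samples above threshold (default 3).
#' @param lib_size Optional per-sample library sizes (default `colSums`).
#' @return list with `retained` (filtered matrix), `excluded` (gene ids),
#'   `n_input`.
#' @export
cpm_filter <- function(counts, min_cpm = 0.25, min_samples = 3L,
                       lib_size = NULL) {
  counts <- as.matrix(counts)
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (any(lib_size <= 0)) stop("zero library size")
  cpm <- sweep(counts, 2, lib_size / 1e6, "/")
  keep <- rowSums(cpm > min_cpm) >= min_samples
  list(retained = counts[keep, , drop = FALSE],
       excluded = rownames(counts)[!keep],
       n_input = nrow(counts))
}

#' TMM library-size normalization factors
#'
#' Trimmed mean of M-values: for each sample, per-gene log2 expression
#' ratios (M) against a reference sample are doubly trimmed (30% on M, 5%
#' on absolute expression A), and the factor is the weighted mean of the
#' surviving M values with inverse asymptotic-variance weights. The
#' reference sample is the library whose upper-quartile CPM is closest to
#' the mean upper quartile. Factors are rescaled so their geometric mean is
#' 1; effective library size = raw library size x factor.
#'
#' @param counts Count matrix (genes x samples), ideally CPM-filtered.
#' @param lib_size Optional library sizes (default `colSums`).
#' @param trim_m,trim_a Two-sided trim fractions on M and A (defaults 0.3,
#'   0.05).
#' @return Named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(counts, lib_size = NULL, trim_m = 0.3,
                        trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (any(lib_size <= 0)) stop("zero library size")
  uq <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib_size
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j)
    tmm_pair(counts[, j], counts[, ref], lib_size[j], lib_size[ref],
             trim_m, trim_a), numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) stop("sample shares no expressed genes with the reference")
  obs <- obs[keep]; ref <- ref[keep]
  p_o <- obs / n_obs; p_r <- ref / n_ref
  m <- log2(p_o / p_r)
  a <- (log2(p_o) + log2(p_r)) / 2
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(m)) < 1e-6) return(1)
  lo_m <- stats::quantile(m, trim_m); hi_m <- stats::quantile(m, 1 - trim_m)
  lo_a <- stats::quantile(a, trim_a); hi_a <- stats::quantile(a, 1 - trim_a)
  keep2 <- m >= lo_m & m <= hi_m & a >= lo_a & a <= hi_a
  if (!any(keep2)) return(1)
  2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

#' Log2 counts-per-million with TMM-effective library sizes
#'
#' @param counts Count matrix.
#' @param factors TMM factors from [tmm_factors()] (default recomputed).
#' @param pseudocount Added to CPM before the log (default 0.5).
#' @return Matrix of `log2(CPM + pseudocount)` values.
#' @export
log_cpm <- function(counts, factors = NULL, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- lib * factors
  log2(sweep(counts, 2, eff / 1e6, "/") + pseudocount)
}

#' RNA-seq style DEG calling on log-CPM values
#'
#' Blocked per-gene tests as in [call_degs()] applied to TMM-normalized
#' log2 CPM, with Benjamini-Yekutieli adjustment and a dual gate
#' `q <= q_level` and `|log2FC| >= min_abs_log2fc` (default 1.3).
#'
#' @param logcpm Matrix of log2 CPM values (genes x samples), e.g. from
#'   [log_cpm()].
#' @param treatment Per-sample labels.
#' @param treat,control Compared labels.
#' @param donor Optional per-sample blocking labels.
#' @param q_level FDR level (default 0.05).
#' @param min_abs_log2fc Fold-change gate (default 1.3).
#' @return As [call_degs()]'s `table` element.
#' @export
rnaseq_degs <- function(logcpm, treatment, treat, control, donor = NULL,
                        q_level = 0.05, min_abs_log2fc = 1.3) {
  m <- as.matrix(logcpm)
  sel <- treatment %in% c(treat, control)
  m <- m[, sel, drop = FALSE]
  grp <- treatment[sel]
  if (!is.null(donor)) donor <- donor[sel]
  i_t <- which(grp == treat); i_c <- which(grp == control)
  if (length(i_t) < 2L || length(i_c) < 2L)
    stop("need >= 2 samples per group")
  log2_fc <- rowMeans(m[, i_t, drop = FALSE]) -
    rowMeans(m[, i_c, drop = FALSE])
  test_mat <- m
  if (!is.null(donor)) {
    for (d in unique(donor)) {
      cols <- donor == d
      test_mat[, cols] <- m[, cols, drop = FALSE] -
        rowMeans(m[, cols, drop = FALSE])
    }
  }
  tt <- row_t_test(test_mat, i_t, i_c)
  adj <- by_adjust(tt$p, q_level)
  large <- abs(log2_fc) >= min_abs_log2fc
  data.frame(
    feature_id = if (is.null(rownames(m))) as.character(seq_len(nrow(m)))
                 else rownames(m),
    log2_fc = log2_fc, p = tt$p, q_value = adj$q_value,
    significant = adj$discovery, large_effect = large,
    discovery = adj$discovery & large,
    direction = ifelse(log2_fc >= 0, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Fraction of total reads carried by the top-k expressed features
#'
#' @param counts Count matrix (genes x samples).
#' @param k Number of top features (by total reads across samples).
#' @return Fraction in (0, 1\].
#' @export
top_expressed_fraction <- function(counts, k) {
  counts <- as.matrix(counts)
  tot <- rowSums(counts)
  if (sum(tot) <= 0) stop("empty count matrix")
  k <- min(k, length(tot))
  sum(sort(tot, decreasing = TRUE)[seq_len(k)]) / sum(tot)
}
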