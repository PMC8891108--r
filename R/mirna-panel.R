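#' Exclude low-expressed features from a cT matrix
#'
#' A feature is excluded when, within any single treatment group, more than
#' `max_fail` replicates have cT above the detection ceiling (default 32
#' cycles). "More than 1 replicate" means a feature with exactly one
#' failing replicate per treatment is retained. By default a feature
#' failing the rule in any group is excluded globally (a feature
#' unmeasurable in one arm cannot be compared across arms);
#' `scope = "all_groups"` instead requires the failure in every group.
#'
#' @param ct Numeric matrix of cT values, features in rows, samples in
#'   columns. Undetected reactions should be encoded above the ceiling
#'   (e.g. `ceiling + 1`).
#' @param treatment Character vector of treatment labels, one per column.
#' @param ceiling Detection ceiling in cycles (default 32).
#' @param max_fail Maximum tolerated failing replicates per treatment
#'   (default 1).
#' @param scope `"any_group"` (default) or `"all_groups"`.
#' @return list with `retained` (filtered matrix), `excluded` (character
#'   vector of dropped feature ids) and `n_input`. Conservation holds:
#'   `nrow(retained) + length(excluded) == n_input`.
#' @export
filter_low_expressed <- function(ct, treatment, ceiling = 32, max_fail = 1L,
                                 scope = c("any_group", "all_groups")) {
  scope <- match.arg(scope)
  ct <- as.matrix(ct)
  if (length(treatment) != ncol(ct))
    stop("one treatment label per sample column required")
  tab <- table(treatment)
  if (any(tab < 2L))
    stop("every treatment needs >= 2 replicates; exclusion rule undefined")
  fails <- vapply(unique(treatment), function(tr)
    rowSums(ct[, treatment == tr, drop = FALSE] > ceiling) > max_fail,
    logical(nrow(ct)))
  fails <- matrix(fails, nrow = nrow(ct))
  drop <- if (scope == "any_group") apply(fails, 1, any) else
    apply(fails, 1, all)
  list(retained = ct[!drop, , drop = FALSE],
       excluded = rownames(ct)[drop],
       n_input = nrow(ct))
}

#' Column-mean normalization of a cT matrix
#'
#' Centers every sample column on its own mean over the retained features,
#' so all column means are exactly 0 afterwards. Idempotent and invariant
#' to per-column shifts; apply after [filter_low_expressed()].
#'
#' @param ct Numeric matrix (features x samples), already filtered.
#' @return Matrix of the same shape with zero column means.
#' @export
normalize_column_mean <- function(ct) {
  ct <- as.matrix(ct)
  if (nrow(ct) == 0L) stop("no retained features to normalize")
  sweep(ct, 2, colMeans(ct))
}

#' Discover deregulated features between a treatment and control
#'
#' Per-feature unpaired t-tests (pooled variance) on normalized cT values,
#' treated vs control, with two-stage adaptive FDR ([bky_two_stage()]) at
#' level `q`. Because lower cT means higher expression, the log2
#' fold-change of expression is `mean(control cT) - mean(treated cT)`
#' (one cycle = one log2 unit under ideal amplification efficiency).
#'
#' @param ct Normalized cT matrix (features x samples).
#' @param treatment Character vector of per-sample labels.
#' @param treat,control Labels of the compared groups (>= 2 replicates
#'   each).
#' @param q FDR level (default 0.01).
#' @param average_technical Optional integer vector mapping columns to
#'   biological units; when supplied, technical replicates are averaged
#'   before testing. Default `NULL` treats every column as a test unit.
#' @return A discovery table: `feature_id`, `log2_fc`, `p`, `q_value`,
#'   `discovery`, `direction` ("up" = higher expression under treatment),
#'   `degenerate`, plus attribute `treatment`.
#' @export
discover_deregulated <- function(ct, treatment, treat, control, q = 0.01,
                                 average_technical = NULL) {
  ct <- as.matrix(ct)
  if (!is.null(average_technical)) {
    stopifnot(length(average_technical) == ncol(ct))
    units <- paste(treatment, average_technical, sep = "\r")
    ct <- sapply(unique(units), function(u)
      rowMeans(ct[, units == u, drop = FALSE]))
    treatment <- sub("\r.*$", "", unique(units))
  }
  i_t <- which(treatment == treat)
  i_c <- which(treatment == control)
  if (length(i_t) < 2L || length(i_c) < 2L)
    stop("need >= 2 replicates in both groups")
  tt <- row_t_test(ct, i_t, i_c)
  log2_fc <- tt$mean2 - tt$mean1     # control cT - treated cT
  adj <- bky_two_stage(tt$p, q)
  out <- data.frame(
    feature_id = if (is.null(rownames(ct))) as.character(seq_len(nrow(ct)))
                 else rownames(ct),
    log2_fc = log2_fc, p = tt$p, q_value = adj$q_value,
    discovery = adj$discovery,
    direction = ifelse(log2_fc >= 0, "up", "down"),
    degenerate = tt$degenerate, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "treatment") <- treat
  out
}

#' Union of discoveries across grouped treatments
#'
#' Pools the discovery sets of several per-treatment tables into named
#' compound groups (e.g. bufalin-like, lycorine-like) as a set union, with
#' per-feature provenance of the member treatments it was discovered in.
#'
#' @param tables Named list of discovery tables (names are treatment
#'   labels).
#' @param grouping Named list mapping group name -> character vector of
#'   member treatment labels.
#' @return Named list, one data.frame per group: `feature_id`, `n_members`
#'   (treatments in which discovered), `members` (comma-separated).
#' @export
group_discoveries <- function(tables, grouping) {
  lapply(grouping, function(members) {
    missing <- setdiff(members, names(tables))
    if (length(missing))
      stop("no discovery table for treatment(s): ",
           paste(missing, collapse = ", "))
    hits <- lapply(members, function(m) {
      t <- tables[[m]]
      t$feature_id[t$discovery]
    })
    names(hits) <- members
    feats <- sort(unique(unlist(hits)))
    if (length(feats) == 0L)
      return(data.frame(feature_id = character(), n_members = integer(),
                        members = character(), stringsAsFactors = FALSE))
    prov <- vapply(feats, function(f)
      paste(members[vapply(hits, function(h) f %in% h, logical(1))],
            collapse = ","), character(1))
    data.frame(feature_id = feats,
               n_members = lengths(regmatches(prov, gregexpr(",", prov))) + 1L,
               members = prov, stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Top candidate features by absolute fold-change among discoveries
#'
#' @param table A discovery table ([discover_deregulated()]).
#' @param k Number of candidates (default 7).
#' @return The `k` discovery rows with the largest `|log2_fc|`, descending;
#'   ties broken by smaller `q_value`, then feature id. Fewer than `k`
#'   discoveries returns them all.
#' @export
top_candidates <- function(table, k = 7L) {
  d <- table[table$discovery, , drop = FALSE]
  ord <- order(-abs(d$log2_fc), d$q_value, d$feature_id)
  out <- d[ord, , drop = FALSE][seq_len(min(k, nrow(d))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
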