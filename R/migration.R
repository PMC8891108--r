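#' Migrative index from scratch-assay open areas
#'
#' Converts open-area measurements of a scratch (wound-healing) assay into
#' fractional closure and, optionally, a control-normalized migrative index
#' (MI). For each well, closure at time `t` is
#' `c(t) = 1 - area(t) / area(t0)`; MI is the closure divided by the mean
#' vehicle-control closure at the same timepoint. Both the raw closure and
#' the normalized MI are always reported. MI at `t0` is 0 by construction.
#'
#' A measured area slightly above the `t0` area (a scratch cannot widen
#' biologically) is clamped to closure 0 with a warning; an excess beyond
#' `tolerance` (relative) is still clamped but flagged in the output.
#'
#' @param areas data.frame with columns `well_id`, `treatment`, `t_hours`,
#'   `open_area` (area units; any unit, MI is ratio-based). Each well needs
#'   a `t_hours == 0` row with positive area.
#' @param control Treatment label of the vehicle control used for
#'   normalization, or `NULL` for unnormalized output only.
#' @param tolerance Relative widening tolerated before flagging (default
#'   0.05).
#' @return data.frame with `well_id`, `treatment`, `t_hours`, `closure`,
#'   `mi` (`NA` when `control` is `NULL` or at timepoints without control
#'   wells), `clamped`.
#' @export
migrative_index <- function(areas, control = "vehicle", tolerance = 0.05) {
  stopifnot(all(c("well_id", "treatment", "t_hours", "open_area")
                %in% names(areas)))
  if (any(areas$open_area < 0)) stop("open areas must be non-negative")
  out <- do.call(rbind, lapply(split(areas, areas$well_id), function(w) {
    a0 <- w$open_area[w$t_hours == 0]
    if (length(a0) != 1L || a0 <= 0)
      stop("well ", w$well_id[1], ": needs exactly one t0 row with area > 0")
    cl <- 1 - w$open_area / a0
    clamped <- cl < -tolerance
    if (any(cl < 0))
      warning("well ", w$well_id[1],
              ": open area above t0 level clamped to closure 0")
    data.frame(well_id = w$well_id, treatment = w$treatment,
               t_hours = w$t_hours, closure = pmax(cl, 0),
               clamped = clamped, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$mi <- NA_real_
  if (!is.null(control)) {
    for (t in unique(out$t_hours)) {
      ctl <- out$closure[out$treatment == control & out$t_hours == t]
      sel <- out$t_hours == t
      if (length(ctl) && mean(ctl) > 0)
        out$mi[sel] <- out$closure[sel] / mean(ctl)
      else if (t == 0)
        out$mi[sel] <- 0
    }
  }
  out
}
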