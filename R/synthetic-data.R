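#' Ground truth for a simulated dose-response screen
#'
#' Bundles everything needed to simulate multi-donor 96-well screens from
#' known four-parameter logistic curves: per-compound true parameters, the
#' dilution series, technical/biological replication, the multiplicative
#' noise level and the plate layout convention (vehicle controls in column
#' 1, full-inhibition controls in column 12, compound doses across the
#' middle columns — a conventional column-edge layout).
#'
#' Curve parameters are on the normalized response scale (1 = vehicle
#' plateau, 0 = assay floor); plate absorbance is
#' `background + (vehicle_abs - background) * response`.
#'
#' @param compounds data.frame with `compound_id`, `top`, `bottom`, `hill`
#'   (> 0), `ec50` (molar, > 0).
#' @param dilutions Strictly decreasing dose series in molar (default a
#'   seven-point 10-fold serial dilution from 1e-5 M, spanning the 5-500 nM
#'   potency window with both plateaus).
#' @param cv Multiplicative (log-normal) noise coefficient of variation,
#'   in \[0, 1).
#' @param n_tech Technical replicates per dose (rows used per plate,
#'   max 8).
#' @param n_bio Biological repetitions (plates per compound).
#' @param n_control Wells per control role (>= 3).
#' @param vehicle_abs,background Absorbance anchors of the vehicle plateau
#'   and the assay floor.
#' @param seed Integer seed owned by this truth object (generators never
#'   touch the global random state).
#' @return Validated list of class `screen_truth`.
#' @export
screen_truth <- function(compounds,
                         dilutions = 1e-5 * 10^-(0:6),
                         cv = 0.05, n_tech = 6L, n_bio = 3L,
                         n_control = 8L, vehicle_abs = 1.8,
                         background = 0.2, seed = 1L) {
  stopifnot(all(c("compound_id", "top", "bottom", "hill", "ec50") %in%
                  names(compounds)))
  if (any(compounds$ec50 <= 0)) stop("ec50 must be > 0")
  if (any(compounds$hill <= 0)) stop("hill must be > 0 (inhibition curves)")
  if (cv < 0 || cv >= 1) stop("cv must lie in [0, 1)")
  if (any(diff(dilutions) >= 0)) stop("dilutions must be strictly decreasing")
  if (n_control < 3L) stop("every plate needs >= 3 wells per control role")
  if (length(dilutions) > 10L || n_tech > 8L)
    stop("layout exceeds a 96-well plate (<= 10 doses, <= 8 technical reps)")
  if (vehicle_abs <= background) stop("vehicle_abs must exceed background")
  structure(list(compounds = compounds, dilutions = dilutions, cv = cv,
                 n_tech = as.integer(n_tech), n_bio = as.integer(n_bio),
                 n_control = as.integer(n_control),
                 vehicle_abs = vehicle_abs, background = background,
                 seed = as.integer(seed)),
            class = "screen_truth")
}

four_pl <- function(dose, top, bottom, hill, ec50)
  bottom + (top - bottom) / (1 + (dose / ec50)^hill)

lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate plate absorbance tables from a screen truth
#'
#' One plate per compound and biological repetition. Expected compound-well
#' absorbance is the true 4PL evaluated at the well's dose, mapped onto the
#' absorbance scale by the control anchors; control wells are drawn around
#' their role means. All wells receive multiplicative log-normal noise with
#' the truth's CV (mean-one, so `cv = 0` reproduces the generating model
#' exactly). Output is bit-identical for identical truths (seeded,
#' no global state).
#'
#' @param truth A [screen_truth()].
#' @return Long data.frame: `plate_id`, `well`, `row`, `col`, `role`
#'   (`negative-control` = vehicle/high signal, `positive-control` =
#'   full inhibition/low signal, `compound`), `compound_id`, `dose_molar`,
#'   `value`.
#' @export
generate_screen <- function(truth) {
  stopifnot(inherits(truth, "screen_truth"))
  nd <- length(truth$dilutions)
  rows <- LETTERS[1:8]
  withr::with_seed(truth$seed, {
    plates <- list()
    for (ci in seq_len(nrow(truth$compounds))) {
      cmp <- truth$compounds[ci, ]
      for (b in seq_len(truth$n_bio)) {
        plate_id <- sprintf("%s_rep%d", cmp$compound_id, b)
        neg <- data.frame(
          plate_id = plate_id,
          row = rows[seq_len(truth$n_control)], col = 1L,
          role = "negative-control", compound_id = NA_character_,
          dose_molar = NA_real_,
          value = truth$vehicle_abs *
            lognormal_factor(truth$n_control, truth$cv))
        pos <- data.frame(
          plate_id = plate_id,
          row = rows[seq_len(truth$n_control)], col = 12L,
          role = "positive-control", compound_id = NA_character_,
          dose_molar = NA_real_,
          value = truth$background *
            lognormal_factor(truth$n_control, truth$cv))
        grid <- expand.grid(tech = seq_len(truth$n_tech),
                            dose_i = seq_len(nd))
        resp <- four_pl(truth$dilutions[grid$dose_i], cmp$top, cmp$bottom,
                        cmp$hill, cmp$ec50)
        mu <- truth$background +
          (truth$vehicle_abs - truth$background) * resp
        cw <- data.frame(
          plate_id = plate_id,
          row = rows[grid$tech], col = grid$dose_i + 1L,
          role = "compound", compound_id = cmp$compound_id,
          dose_molar = truth$dilutions[grid$dose_i],
          value = mu * lognormal_factor(nrow(grid), truth$cv))
        plates[[plate_id]] <- rbind(neg, pos, cw)
      }
    }
    out <- do.call(rbind, plates)
    out$well <- paste0(out$row, out$col)
    rownames(out) <- NULL
    out[, c("plate_id", "well", "row", "col", "role", "compound_id",
            "dose_molar", "value")]
  })
}

#' Ground truth for simulated omics matrices
#'
#' Parameters of the qPCR-array (cT) and count-panel generators: which
#' features are expressed, which carry spiked deregulation (and how much),
#' the treatment x replicate design, donor/lot effects, dispersion and the
#' reference-gene subset. Spiked features must be expressed; reference
#' genes carry no spiked effect by construction.
#'
#' @param n_features Total features.
#' @param expressed Integer indices of expressed features.
#' @param spiked data.frame with `feature` (index), `treatment`, `log2fc`;
#'   may be empty.
#' @param treatments Character vector of treatment labels (must include
#'   `control`).
#' @param control Control label (default "control").
#' @param n_replicates Samples per treatment (cT design: technical x
#'   passage replicates; panel design: one per donor).
#' @param donors Donor/lot labels for count panels (`NULL` for none).
#' @param donor_sd SD of per-donor log-scale offsets (default 0.3).
#' @param dispersion Negative-binomial dispersion (default 0.02; 0 gives
#'   Poisson counts).
#' @param reference_genes Integer indices of reference genes (zero effect).
#' @param ct_sd Per-well cT noise SD in cycles (default 0.5).
#' @param seed Integer seed.
#' @return Validated list of class `omics_truth`.
#' @export
omics_truth <- function(n_features, expressed,
                        spiked = data.frame(feature = integer(),
                                            treatment = character(),
                                            log2fc = numeric()),
                        treatments = c("control", "treated"),
                        control = "control",
                        n_replicates = 6L, donors = NULL, donor_sd = 0.3,
                        dispersion = 0.02, reference_genes = integer(),
                        ct_sd = 0.5, seed = 1L) {
  if (!control %in% treatments) stop("treatments must include the control")
  if (any(!expressed %in% seq_len(n_features)))
    stop("expressed indices out of range")
  if (nrow(spiked)) {
    if (any(!spiked$feature %in% expressed))
      stop("spiked effect assigned to unexpressed feature")
    if (any(spiked$feature %in% reference_genes))
      stop("reference genes must carry no spiked effect")
    if (any(!spiked$treatment %in% setdiff(treatments, control)))
      stop("spiked treatments must be non-control treatments")
  }
  if (any(!reference_genes %in% expressed))
    stop("reference genes must be expressed")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (n_replicates < 2L) stop("need >= 2 replicates per treatment")
  structure(list(n_features = as.integer(n_features),
                 expressed = as.integer(expressed), spiked = spiked,
                 treatments = treatments, control = control,
                 n_replicates = as.integer(n_replicates), donors = donors,
                 donor_sd = donor_sd, dispersion = dispersion,
                 reference_genes = as.integer(reference_genes),
                 ct_sd = ct_sd, seed = as.integer(seed)),
            class = "omics_truth")
}

#' Simulate a qPCR-array cT matrix
#'
#' Expressed features get a per-feature baseline cT drawn uniformly in
#' 18-30 cycles; unexpressed features sit around 36 +/- 1.5 cycles, above
#' the usual detection ceiling of 32 with high probability. A spiked
#' log2 fold-change shifts the treated-group mean cT by `-log2fc` cycles
#' (lower cT = higher expression). Per-well noise is Gaussian with the
#' truth's `ct_sd`.
#'
#' @param truth An [omics_truth()].
#' @return list with `ct` (matrix, features x samples), `samples`
#'   (data.frame `sample_id`, `treatment`, `replicate`) and `baseline`
#'   (true per-feature baseline cT).
#' @export
generate_ct_matrix <- function(truth) {
  stopifnot(inherits(truth, "omics_truth"))
  nf <- truth$n_features
  trts <- truth$treatments
  withr::with_seed(truth$seed, {
    baseline <- stats::rnorm(nf, 36, 1.5)
    baseline[truth$expressed] <- stats::runif(length(truth$expressed), 18, 30)
    samples <- expand.grid(replicate = seq_len(truth$n_replicates),
                           treatment = trts, stringsAsFactors = FALSE)
    samples$sample_id <- paste(samples$treatment, samples$replicate,
                               sep = "_")
    ct <- matrix(0, nf, nrow(samples),
                 dimnames = list(sprintf("miR_%03d", seq_len(nf)),
                                 samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mu <- baseline
      if (nrow(truth$spiked)) {
        sp <- truth$spiked[truth$spiked$treatment == samples$treatment[j], ]
        if (nrow(sp)) mu[sp$feature] <- mu[sp$feature] - sp$log2fc
      }
      ct[, j] <- stats::rnorm(nf, mu, truth$ct_sd)
    }
    list(ct = ct,
         samples = samples[, c("sample_id", "treatment", "replicate")],
         baseline = baseline)
  })
}

#' Simulate a reference-gene-anchored count panel
#'
#' Negative-binomial counts with log-linear treatment and donor effects:
#' gene baselines are log-normal (median ~500 counts), each donor/lot
#' applies a shared multiplicative offset (SD `donor_sd` on the log scale)
#' and spiked genes are multiplied by `2^log2fc` in their treatment.
#' Reference genes are expressed and unaffected by treatment, so their
#' expectation is constant across treatments within a donor. One sample is
#' generated per treatment x donor combination. `dispersion = 0` is the
#' Poisson limit (counts concentrate on the group means).
#'
#' @param truth An [omics_truth()] with non-`NULL` `donors`.
#' @return list with `counts` (matrix), `samples` (`sample_id`,
#'   `treatment`, `replicate`, `donor`), `baseline` (true per-gene baseline
#'   mean) and `reference_genes` (ids).
#' @export
generate_panel_counts <- function(truth) {
  stopifnot(inherits(truth, "omics_truth"))
  if (is.null(truth$donors)) stop("panel generation needs donor labels")
  nf <- truth$n_features
  gene_ids <- sprintf("gene_%03d", seq_len(nf))
  gene_ids[truth$reference_genes] <-
    sprintf("ref_%02d", seq_along(truth$reference_genes))
  withr::with_seed(truth$seed, {
    baseline <- exp(stats::rnorm(nf, log(500), 1))
    baseline[-truth$expressed] <- 0.05   # unexpressed: background counts
    donor_off <- stats::rnorm(length(truth$donors), 0, truth$donor_sd)
    names(donor_off) <- truth$donors
    samples <- expand.grid(donor = truth$donors,
                           treatment = truth$treatments,
                           stringsAsFactors = FALSE)
    samples$sample_id <- paste(samples$treatment, samples$donor, sep = "_")
    samples$replicate <- as.integer(factor(samples$donor,
                                           levels = truth$donors))
    counts <- matrix(0L, nf, nrow(samples),
                     dimnames = list(gene_ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mu <- baseline * exp(donor_off[samples$donor[j]])
      if (nrow(truth$spiked)) {
        sp <- truth$spiked[truth$spiked$treatment == samples$treatment[j], ]
        if (nrow(sp)) mu[sp$feature] <- mu[sp$feature] * 2^sp$log2fc
      }
      counts[, j] <- if (truth$dispersion == 0) stats::rpois(nf, mu)
        else stats::rnbinom(nf, size = 1 / truth$dispersion, mu = mu)
    }
    list(counts = counts,
         samples = samples[, c("sample_id", "treatment", "replicate",
                               "donor")],
         baseline = baseline, reference_genes = gene_ids[truth$reference_genes])
  })
}

#' Simulate a long-tailed RNA-seq-like count matrix
#'
#' Relative transcript abundances combine a handful of explicitly dominant
#' transcripts (default shares calibrated so the single top transcript
#' carries ~3.3% of reads and the top six together exceed 10%) with a
#' log-normal tail over the remaining genes. Counts are negative binomial
#' at the given depth; spiked genes are multiplied by `2^log2fc` in their
#' treatment.
#'
#' @param n_genes Number of genes (default 5000).
#' @param top_shares Read shares of the dominant transcripts (defaults sum
#'   to ~0.103 over six transcripts).
#' @param spiked data.frame `feature`, `treatment`, `log2fc`.
#' @param treatments,control,n_replicates Design (defaults: control vs
#'   treated, 3 each).
#' @param lib_size Expected reads per sample (default 2e6).
#' @param dispersion NB dispersion (default 0.05).
#' @param seed Integer seed.
#' @return list with `counts`, `samples`, `shares` (true relative
#'   abundances).
#' @export
generate_rnaseq_counts <- function(n_genes = 5000L,
                                   top_shares = c(0.033, 0.020, 0.013,
                                                  0.013, 0.012, 0.012),
                                   spiked = data.frame(feature = integer(),
                                                       treatment = character(),
                                                       log2fc = numeric()),
                                   treatments = c("control", "treated"),
                                   control = "control",
                                   n_replicates = 3L, lib_size = 2e6,
                                   dispersion = 0.05, seed = 1L) {
  if (sum(top_shares) >= 1) stop("top shares must sum to < 1")
  withr::with_seed(as.integer(seed), {
    n_top <- length(top_shares)
    tail_w <- exp(stats::rnorm(n_genes - n_top, 0, 1.5))
    shares <- c(top_shares, (1 - sum(top_shares)) * tail_w / sum(tail_w))
    samples <- expand.grid(replicate = seq_len(n_replicates),
                           treatment = treatments, stringsAsFactors = FALSE)
    samples$sample_id <- paste(samples$treatment, samples$replicate,
                               sep = "_")
    counts <- matrix(0L, n_genes, nrow(samples),
                     dimnames = list(sprintf("tx_%05d", seq_len(n_genes)),
                                     samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mu <- shares * lib_size
      if (nrow(spiked)) {
        sp <- spiked[spiked$treatment == samples$treatment[j], ]
        if (nrow(sp)) mu[sp$feature] <- mu[sp$feature] * 2^sp$log2fc
      }
      counts[, j] <- stats::rnbinom(n_genes, size = 1 / dispersion, mu = mu)
    }
    list(counts = counts,
         samples = samples[, c("sample_id", "treatment", "replicate")],
         shares = shares)
  })
}

# ---- scenario presets ------------------------------------------------------

#' Scenario presets mirroring the study designs
#'
#' `preset_mirna_truth()`: 754-feature cT array with 165 expressed
#' features, 20 of them spiked by 3 cycles (half up, half down) in the
#' treated arm, 6 samples (2 technical x 3 passages) per treatment.
#' `preset_panel_truth()`: 770-gene count panel with 10 reference genes,
#' 3 donors, 60 genes spiked at |log2FC| = 2 (half up, half down).
#' `preset_screen_truth()`: one compound per EC50 in \{5, 50, 500\} nM on a
#' 7-point 10-fold serial dilution with 6 technical replicates at 5% CV.
#'
#' Every dimension is configurable through the underlying constructors;
#' these presets only fix the scales.
#'
#' @param seed Integer seed.
#' @param n_spiked Number of spiked features.
#' @param log2fc Spiked effect size (cycles for cT, log2 units for counts).
#' @name presets
NULL

#' @rdname presets
#' @export
preset_mirna_truth <- function(seed = 1L, n_spiked = 20L, log2fc = 3) {
  expressed <- seq_len(165L)
  # both directions, as observed deregulation runs both ways; a one-sided
  # spike set would also bias column-mean normalization (see vignette)
  spiked <- data.frame(feature = seq_len(n_spiked), treatment = "treated",
                       log2fc = rep(c(log2fc, -log2fc),
                                    length.out = n_spiked))
  omics_truth(n_features = 754L, expressed = expressed, spiked = spiked,
              treatments = c("control", "treated"), n_replicates = 6L,
              seed = seed)
}

#' @rdname presets
#' @export
preset_panel_truth <- function(seed = 1L, n_spiked = 60L, log2fc = 2) {
  expressed <- seq_len(770L)
  sp_feat <- seq(11L, length.out = n_spiked)
  spiked <- data.frame(feature = sp_feat, treatment = "treated",
                       log2fc = rep(c(log2fc, -log2fc),
                                    length.out = n_spiked))
  omics_truth(n_features = 770L, expressed = expressed, spiked = spiked,
              treatments = c("control", "treated"), n_replicates = 3L,
              donors = c("donor1", "donor2", "donor3"),
              reference_genes = seq_len(10L), seed = seed)
}

#' @rdname presets
#' @export
preset_screen_truth <- function(seed = 1L) {
  screen_truth(
    compounds = data.frame(
      compound_id = c("cmp_5nM", "cmp_50nM", "cmp_500nM"),
      top = 1, bottom = 0, hill = 1,
      ec50 = c(5e-9, 5e-8, 5e-7)),
    seed = seed)
}

# ---- plain-text interchange ------------------------------------------------

#' Write / read the pipeline's plain-text formats
#'
#' Plate tables go to CSV; feature matrices to TSV (features in rows,
#' sample ids in the header) with a sample-annotation TSV alongside; truth
#' objects to JSON for use as test oracles.
#'
#' @param x Object to write.
#' @param path Output path.
#' @name io
NULL

#' @rdname io
#' @export
write_plate_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname io
#' @export
read_plate_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("plate_id", "well", "row", "col", "role", "compound_id",
              "dose_molar", "value")
  if (!all(needed %in% names(tab)))
    stop("plate CSV must have columns: ", paste(needed, collapse = ", "))
  tab
}

#' @rdname io
#' @param samples Sample annotation data.frame.
#' @export
write_feature_matrix <- function(x, samples, path) {
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann_path <- sub("(\\.tsv)?$", "_samples.tsv", path)
  utils::write.table(samples, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, ann_path))
}

#' @rdname io
#' @export
read_feature_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  ann_path <- sub("(\\.tsv)?$", "_samples.tsv", path)
  samples <- if (file.exists(ann_path))
    utils::read.delim(ann_path, stringsAsFactors = FALSE) else NULL
  list(matrix = m, samples = samples)
}

#' @rdname io
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}
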