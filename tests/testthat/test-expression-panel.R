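test_that("reference-gene normalization equalizes housekeeping geomeans", {
  withr::with_seed(71, {
    m <- matrix(rnbinom(100 * 6, mu = 300, size = 20), 100,
                dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
    refs <- paste0("g", 1:5)
    # identical samples: all factors 1
    same <- m[, c(1, 1, 1)]
    colnames(same) <- paste0("s", 1:3)
    expect_equal(unname(normalize_reference_genes(same, refs)$factors),
                 rep(1, 3))
    # doubling one sample doubles its factor and undoes itself
    doubled <- m
    doubled[, 2] <- doubled[, 2] * 2
    r <- normalize_reference_genes(doubled, refs)
    r0 <- normalize_reference_genes(m, refs)
    # scale equivariance: relative to the other samples, the doubled
    # sample's factor doubles, and the normalized matrices agree up to the
    # global anchor (the across-sample mean of reference geomeans)
    expect_equal(unname((r$factors[2] / r$factors[1]) /
                          (r0$factors[2] / r0$factors[1])), 2,
                 tolerance = 1e-12)
    anchor <- mean(r$normalized) / mean(r0$normalized)
    expect_equal(r$normalized, r0$normalized * anchor, tolerance = 1e-9)
    # reference geometric means equal across samples afterwards
    geo <- exp(colMeans(log(r$normalized[refs, ])))
    expect_lt(diff(range(geo)) / mean(geo), 1e-9)
  })
  # zero-count reference genes are dropped from the factor with a warning
  m2 <- matrix(c(10, 10, 0, 10, 20, 20, 5, 20), 4,
               dimnames = list(c("r1", "r2", "r3", "g4"), c("a", "b")))
  expect_warning(r2 <- normalize_reference_genes(m2, c("r1", "r2", "r3")),
                 "zero counts")
  expect_setequal(r2$used_reference_genes, c("r1", "r2"))
  expect_error(suppressWarnings(
    normalize_reference_genes(m2, c("r3", "g4"))), "fewer than 2")
})

test_that("identical groups produce no DEGs and the effect gate is enforced", {
  withr::with_seed(72, {
    half <- matrix(rnbinom(200 * 3, mu = 400, size = 50), 200,
                   dimnames = list(paste0("g", 1:200), NULL))
    m <- cbind(half, half)
    colnames(m) <- paste0("s", 1:6)
  })
  trt <- rep(c("control", "treated"), each = 3)
  r <- call_degs(m, trt, "treated", "control")
  expect_equal(sum(r$table$discovery), 0)

  # a clearly significant 0.9 log2FC gene fails the |log2FC| >= 1 gate
  g <- 2^c(10, 10, 10, 10.9, 10.9, 10.9)
  m2 <- rbind(matrix(rep(g, 50), 50, byrow = TRUE) *
                matrix(exp(rnorm(300, 0, 0.01)), 50),
              gate = g)
  rownames(m2)[1:50] <- paste0("f", 1:50)
  m2["gate", ] <- m2["gate", ] * exp(c(0.001, -0.001, 0, 0.001, -0.001, 0))
  r2 <- call_degs(m2, trt, "treated", "control")$table
  gate_row <- r2[r2$feature_id == "gate", ]
  expect_true(gate_row$significant)
  expect_false(gate_row$large_effect)
  expect_false(gate_row$discovery)
})

test_that("all-zero genes are excluded from testing with a record", {
  m <- rbind(live = c(10, 12, 9, 30, 33, 31), dead = rep(0, 6))
  trt <- rep(c("control", "treated"), each = 3)
  r <- call_degs(m, trt, "treated", "control")
  expect_equal(r$excluded, "dead")
  expect_equal(r$table$feature_id, "live")
})

test_that("donor blocking absorbs lot effects the unblocked test inherits", {
  tr <- omics_truth(300, expressed = 1:300,
                    spiked = data.frame(feature = 1:20,
                                        treatment = "treated",
                                        log2fc = rep(c(2, -2), 10)),
                    n_replicates = 3, donors = paste0("d", 1:3),
                    donor_sd = 0.6, reference_genes = 291:300, seed = 73)
  pc <- generate_panel_counts(tr)
  nr <- normalize_reference_genes(pc$counts, pc$reference_genes)
  blocked <- call_degs(nr$normalized, pc$samples$treatment, "treated",
                       "control", donor = pc$samples$donor)$table
  spikes <- rownames(pc$counts)[1:20]
  expect_gte(sum(blocked$discovery & blocked$feature_id %in% spikes), 16)
})

test_that("shared-DEG sets classify all/near/conflict cases exactly", {
  mk <- function(dirs) {
    # dirs: named direction per discovered gene in this table
    data.frame(feature_id = names(dirs), discovery = TRUE,
               direction = unname(dirs), stringsAsFactors = FALSE)
  }
  tabs <- list(
    t1 = mk(c(gA = "up", gB = "up", gC = "up")),
    t2 = mk(c(gA = "up", gB = "up", gC = "down")),
    t3 = mk(c(gA = "up", gB = "up", gC = "up")),
    t4 = mk(c(gA = "up", gB = "up", gC = "up")),
    t5 = mk(c(gA = "up", gB = "up", gC = "down")),
    t6 = mk(c(gA = "up", gC = "down")))
  s <- shared_deg_sets(tabs, min_conditions = 5)
  expect_equal(s$all$feature_id, "gA")      # same direction in all 6
  expect_equal(s$near$feature_id, "gB")     # up in 5 of 6
  expect_equal(s$near$n_conditions, 5L)
  expect_equal(s$conflicts, "gC")           # up in 3, down in 3
  expect_length(intersect(s$all$feature_id, s$near$feature_id), 0)
  expect_error(shared_deg_sets(tabs[1]), ">= 2")
})

test_that("signature scores are centered mean expressions per condition", {
  expr <- rbind(g1 = c(1, 1, 5, 5), g2 = c(2, 2, 4, 4), g3 = c(0, 0, 0, 0))
  cond <- rep(c("ctl", "trt"), each = 2)
  s <- pathway_signature_scores(expr, list(pw = c("g1", "g2"),
                                           single = "g1"), cond)
  pw <- s[s$pathway == "pw", ]
  # condition means: ctl (1+2)/2 = 1.5, trt (5+4)/2 = 4.5; centered +/- 1.5
  expect_equal(pw$score, c(1.5, 4.5))
  expect_equal(pw$normalized_score, c(-1.5, 1.5))
  single <- s[s$pathway == "single", ]
  expect_equal(single$normalized_score, c(-2, 2))
  expect_equal(sum(pw$normalized_score), 0)
  # identical conditions: all normalized scores zero
  s2 <- pathway_signature_scores(expr[, c(1, 2, 1, 2)],
                                 list(pw = c("g1", "g2")), cond)
  expect_equal(s2$normalized_score, c(0, 0))
  expect_message(pathway_signature_scores(expr, list(none = "gX"), cond),
                 "skipped")
})

test_that("GMT gene sets round-trip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pathA\tdesc\tg1\tg2\tg3", "pathB\tdesc\tg9"), path)
  sets <- read_gmt(path)
  expect_equal(sets, list(pathA = c("g1", "g2", "g3"), pathB = "g9"))
})

test_that("the CPM filter decides its boundary cases exactly as stated", {
  lib <- rep(1e7, 6)
  counts <- rbind(
    in3 = c(3, 3, 3, 0, 0, 0),    # 0.3 CPM in exactly 3 samples
    in2 = c(3, 3, 0, 0, 0, 0),    # only 2 samples above threshold
    at_thr = c(2.5, 2.5, 2.5, 2.5, 0, 0),  # exactly 0.25 CPM: not > 0.25
    zero = rep(0, 6))
  counts <- counts * 1  # numeric
  r <- cpm_filter(counts, lib_size = lib)
  expect_equal(rownames(r$retained), "in3")
  expect_setequal(r$excluded, c("in2", "at_thr", "zero"))
  expect_equal(nrow(r$retained) + length(r$excluded), r$n_input)
  expect_error(cpm_filter(counts, lib_size = rep(0, 6)), "zero library")
})

test_that("TMM factors are 1 for identical composition and match edgeR otherwise", {
  withr::with_seed(74, {
    base <- rnbinom(500, mu = 200, size = 5) + 1
    m <- cbind(s1 = base, s2 = base, s3 = 2L * base)  # pure depth change
    f <- tmm_factors(m)
    expect_equal(unname(f), rep(1, 3), tolerance = 1e-9)
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)

    # composition bias: a block of genes highly expressed in one sample only
    m2 <- matrix(rnbinom(2000 * 4, mu = 100, size = 10) + 1, 2000)
    m2[1:60, 4] <- m2[1:60, 4] * 30
    colnames(m2) <- paste0("s", 1:4)
    ours <- tmm_factors(m2)
    theirs <- edgeR::calcNormFactors(m2, method = "TMM")
    expect_equal(unname(ours), unname(theirs), tolerance = 0.05)
  })
})

test_that("stricter DEG thresholds always select subsets", {
  tr <- omics_truth(400, expressed = 1:400,
                    spiked = data.frame(feature = 1:40,
                                        treatment = "treated",
                                        log2fc = rep(c(1.5, -1.5, 3, -3), 10)),
                    n_replicates = 3, donors = paste0("d", 1:3),
                    reference_genes = 391:400, seed = 75)
  pc <- generate_panel_counts(tr)
  nr <- normalize_reference_genes(pc$counts, pc$reference_genes)
  loose <- call_degs(nr$normalized, pc$samples$treatment, "treated",
                     "control", donor = pc$samples$donor,
                     q_level = 0.05, min_abs_log2fc = 1)$table
  strict <- call_degs(nr$normalized, pc$samples$treatment, "treated",
                      "control", donor = pc$samples$donor,
                      q_level = 0.01, min_abs_log2fc = 2)$table
  expect_true(all(strict$feature_id[strict$discovery] %in%
                    loose$feature_id[loose$discovery]))
})

test_that("RNA-seq DEG calling gates on BY FDR and 1.3 log2 fold-change", {
  # spiked genes at |log2FC| = 1.2 stay below the effect gate
  withr::with_seed(76, {
    rs <- generate_rnaseq_counts(
      n_genes = 1000,
      spiked = data.frame(feature = 7:26, treatment = "treated",
                          log2fc = rep(c(1.2, -1.2), 10)),
      seed = 77)
  })
  lc <- log_cpm(cpm_filter(rs$counts)$retained)
  d <- rnaseq_degs(lc, rs$samples$treatment, "treated", "control")
  spikes <- rownames(rs$counts)[7:26]
  expect_equal(sum(d$discovery[d$feature_id %in% spikes]), 0)
  # null matrix: BY is conservative, approximately zero DEGs
  null <- generate_rnaseq_counts(n_genes = 1000, seed = 78)
  lcn <- log_cpm(cpm_filter(null$counts)$retained)
  dn <- rnaseq_degs(lcn, null$samples$treatment, "treated", "control")
  expect_lte(sum(dn$discovery), 2)
})

test_that("top-expressed fractions behave on edge cases and the preset", {
  m <- matrix(1, 10, 2)
  expect_equal(top_expressed_fraction(m, 10), 1)
  expect_equal(top_expressed_fraction(m, 5), 0.5)
  rs <- generate_rnaseq_counts(n_genes = 3000, seed = 79)
  expect_gt(top_expressed_fraction(rs$counts, 6), 0.10)
})
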