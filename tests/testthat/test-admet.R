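# explicit rubric used throughout: results never depend on shipped defaults
test_rubric <- function() {
  admet_rubric(list(
    mw = list(category = "physicochemical",
              values = c(0, 1), scores = c(0, 30)),
    sol = list(category = "physicochemical",
               map = list(Low = 0, Mid = 15, High = 30)),
    absorption = list(category = "pharmacokinetics",
                      map = list(Poor = 0, Good = 30)),
    lip = list(category = "drug-likeness",
               values = c(0, 4), scores = c(30, 0)),
    pains = list(category = "medicinal chemistry",
                 values = c(0, 3), scores = c(30, 0)),
    fbio = list(category = "bioavailability",
                values = c(0, 1), scores = c(0, 30))))
}

test_that("rubric scoring hits its endpoints and interpolates linearly", {
  rub <- test_rubric()
  expect_equal(score_parameter("High", "sol", rub), 30)
  expect_equal(score_parameter("Low", "sol", rub), 0)
  expect_equal(score_parameter(0.5, "mw", rub), 15)   # midpoint of 0->0, 1->30
  expect_equal(score_parameter(2, "mw", rub), 30)     # clamped beyond anchor
  expect_error(score_parameter(1, "unknown_param", rub), "not in rubric")
  expect_error(score_parameter("Soluble", "sol", rub), "not a rubric level")
  expect_error(admet_rubric(list(x = list(category = "physicochemical",
                                          values = c(0, 1),
                                          scores = c(0, 40)))),
               "outside")
})

test_that("the shipped default rubric is itself valid", {
  path <- system.file("extdata", "admet_rubric.yaml", package = "fibroscreen")
  rub <- read_rubric(path)
  expect_s3_class(rub, "admet_rubric")
  expect_equal(score_parameter("High", "gi_absorption", rub), 30)
})

profile_at <- function(level) {
  rub <- test_rubric()
  vals <- if (level == "best")
    list(mw = 1, sol = "High", absorption = "Good", lip = 0, pains = 0,
         fbio = 1)
  else
    list(mw = 0, sol = "Low", absorption = "Poor", lip = 4, pains = 3,
         fbio = 0)
  tab <- data.frame(compound_id = "c", parameter = names(vals),
                    value = unlist(lapply(vals, as.character)),
                    stringsAsFactors = FALSE)
  score_admet_table(tab, rub)
}

test_that("the weighted prediction score spans exactly 0 to 30", {
  expect_equal(prediction_score(profile_at("best"))$prediction_score, 30)
  expect_equal(prediction_score(profile_at("worst"))$prediction_score, 0)
  # category means (30, 0, 0, 0, 0) with weights (2,3,2,1,1) -> 60/9
  scored <- data.frame(
    category = names(admet_categories()),
    score = c(30, 0, 0, 0, 0))
  expect_equal(prediction_score(scored)$prediction_score, 60 / 9)
  expect_error(prediction_score(scored[-2, ]), "empty category")
})

test_that("raising any parameter score never lowers the total", {
  withr::with_seed(51, {
    cats <- names(admet_categories())
    for (i in 1:30) {
      scored <- data.frame(category = sample(cats, 12, replace = TRUE),
                           score = runif(12, 0, 30))
      scored$category[1:5] <- cats   # ensure all populated
      base <- prediction_score(scored)$prediction_score
      j <- sample(12, 1)
      bumped <- scored
      bumped$score[j] <- min(30, bumped$score[j] + runif(1, 0, 10))
      expect_gte(prediction_score(bumped)$prediction_score, base - 1e-12)
    }
  })
})

test_that("equal weights reduce the score to the plain mean of category means", {
  withr::with_seed(52, {
    cats <- names(admet_categories())
    scored <- data.frame(category = rep(cats, each = 3),
                         score = runif(15, 0, 30))
    eq <- setNames(rep(1, 5), cats)
    r <- prediction_score(scored, weights = eq)
    expect_equal(r$prediction_score, mean(r$category_means))
  })
})

test_that("working-set selection follows the rank product with EC50 tie-break", {
  tab <- data.frame(compound_id = c("a", "b", "c", "d"),
                    ec50 = c(1e-9, 5e-9, 1e-8, 1e-6),
                    prediction_score = c(25, 20, 28, 10),
                    active = TRUE)
  sel <- select_working_set(tab, k = 2)
  expect_equal(sel$compound_id[1], "a")  # dominates on neither ranked last
  # tie on rank product resolved by the lower EC50
  tie <- data.frame(compound_id = c("x", "y"),
                    ec50 = c(1e-9, 1e-8),
                    prediction_score = c(10, 20), active = TRUE)
  st <- select_working_set(tie, k = 1)
  expect_equal(st$rank_product, c(2, 2))
  expect_equal(st$compound_id[1], "x")
  expect_warning(select_working_set(tab, k = 10), "fewer than k")
})

test_that("rank-product ordering matches exhaustive enumeration and is rank-invariant", {
  withr::with_seed(53, {
    for (i in 1:40) {
      n <- sample(4:12, 1)
      tab <- data.frame(compound_id = sprintf("c%02d", 1:n),
                        ec50 = 10^runif(n, -9, -5),
                        prediction_score = runif(n, 0, 30), active = TRUE)
      sel <- select_working_set(tab, k = 3)
      # enumeration oracle: count-based ranks and explicit product
      r1 <- vapply(tab$ec50, function(e) sum(tab$ec50 < e) + 1, numeric(1))
      r2 <- vapply(tab$prediction_score,
                   function(s) sum(tab$prediction_score > s) + 1, numeric(1))
      ord <- tab$compound_id[order(r1 * r2, tab$ec50, tab$compound_id)]
      expect_equal(sel$compound_id, ord)
      # monotone transform of EC50 leaves the selection unchanged
      tab2 <- tab
      tab2$ec50 <- rank(tab$ec50) + 100
      expect_equal(select_working_set(tab2, k = 3)$compound_id,
                   sel$compound_id)
    }
  })
})

test_that("Pareto-front ordering puts non-dominated compounds first", {
  tab <- data.frame(compound_id = c("dom", "mid", "bad"),
                    ec50 = c(1e-9, 1e-8, 1e-7),
                    prediction_score = c(30, 20, 10), active = TRUE)
  sel <- select_working_set(tab, k = 3, method = "pareto")
  expect_equal(sel$pareto_front, c(1, 2, 3))
})

test_that("the minimal SDF reader extracts atoms and bonds", {
  path <- write_sdf_fixture(list(sdf_ethanol(), sdf_methane()))
  mols <- read_sdf(path)
  expect_length(mols, 2)
  expect_equal(mols[[1]]$atoms, c("C", "C", "O"))
  expect_equal(nrow(mols[[1]]$bonds), 2)
  expect_equal(mols[[2]]$atoms, "C")
  bad <- write_sdf_fixture(list(sdf_ethanol(), c("broken", "x", "", "junk",
                                                 "$$$$")))
  expect_error(read_sdf(bad), "record 2")
})

test_that("fingerprints are canonical under atom renumbering", {
  p1 <- write_sdf_fixture(list(sdf_ethanol()))
  p2 <- write_sdf_fixture(list(sdf_ethanol_permuted()))
  f1 <- fingerprint(read_sdf(p1)[[1]])
  f2 <- fingerprint(read_sdf(p2)[[1]])
  expect_identical(f1$bits, f2$bits)
  expect_equal(tanimoto(f1, f2), 1)
  # single heavy atom: exactly the one 1-atom path bit
  fm <- fingerprint(read_sdf(write_sdf_fixture(list(sdf_methane())))[[1]])
  expect_length(fm$bits, 1)
  # hydrogens are suppressed before path enumeration
  eth_h <- sdf_record("ethanol_h", c("C", "C", "O", "H"),
                      c(sdf_bond_line(1, 2), sdf_bond_line(2, 3),
                        sdf_bond_line(3, 4)))
  fh <- fingerprint(read_sdf(write_sdf_fixture(list(eth_h)))[[1]])
  expect_identical(fh$bits, f1$bits)
})

test_that("Tanimoto similarity is exact set arithmetic", {
  fp <- function(bits) structure(list(bits = as.integer(bits),
                                      length = 1024L),
                                 class = "fingerprint")
  expect_equal(tanimoto(fp(c(1, 5, 9)), fp(c(1, 5, 9))), 1)
  expect_equal(tanimoto(fp(1:3), fp(4:6)), 0)
  expect_equal(tanimoto(fp(1:3), fp(2:4)), 0.5)
  expect_equal(tanimoto(fp(integer()), fp(integer())), 0)
  expect_error(tanimoto(fp(1), structure(list(bits = 1L, length = 512L),
                                         class = "fingerprint")),
               "length mismatch")
  m <- tanimoto_matrix(list(a = fp(1:3), b = fp(2:4), c = fp(10:12)))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), c(1, 1, 1))
})
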