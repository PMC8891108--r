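#' ADMET category labels
#'
#' The five prediction categories and their default weights (2, 3, 2, 1, 1)
#' used by [prediction_score()].
#' @export
admet_categories <- function() {
  c(physicochemical = 2, pharmacokinetics = 3, `drug-likeness` = 2,
    `medicinal chemistry` = 1, bioavailability = 1)
}

#' Read an ADMET scoring rubric
#'
#' A rubric maps each predicted parameter to a category and a scoring rule
#' on the 0 (worst) to 30 (optimal) scale. Two rule types exist:
#' \describe{
#'   \item{categorical}{`map`: named list level -> score.}
#'   \item{numeric}{`values` and `scores`: anchor points; raw values are
#'     linearly interpolated between anchors and clamped at the ends.}
#' }
#' A documented default rubric for common in-silico ADMET outputs ships in
#' `system.file("extdata", "admet_rubric.yaml", package = "fibroscreen")`.
#'
#' @param path YAML rubric file.
#' @return Named list of validated rubric entries (class `admet_rubric`).
#' @export
read_rubric <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_rubric(raw)
}

#' Build a scoring rubric from a list of entries
#'
#' Programmatic counterpart of [read_rubric()]: validates and classes a
#' named list of rubric entries (see [read_rubric()] for the entry format).
#'
#' @param entries Named list of rubric entries.
#' @return An `admet_rubric`.
#' @export
admet_rubric <- function(entries) validate_rubric(entries)

validate_rubric <- function(raw) {
  cats <- names(admet_categories())
  for (pname in names(raw)) {
    e <- raw[[pname]]
    if (is.null(e$category) || !e$category %in% cats)
      stop("rubric entry '", pname, "' has unknown category")
    if (!is.null(e$map)) {
      s <- unlist(e$map)
      if (any(s < 0 | s > 30))
        stop("rubric entry '", pname, "': scores outside [0, 30]")
    } else if (!is.null(e$values)) {
      if (length(e$values) != length(e$scores) || length(e$values) < 2L)
        stop("rubric entry '", pname, "': values/scores anchor mismatch")
      if (any(e$scores < 0 | e$scores > 30))
        stop("rubric entry '", pname, "': scores outside [0, 30]")
      if (is.unsorted(e$values, strictly = TRUE))
        stop("rubric entry '", pname, "': anchor values must be increasing")
    } else stop("rubric entry '", pname, "' defines neither map nor anchors")
  }
  structure(raw, class = "admet_rubric")
}

#' Score one raw ADMET parameter value against the rubric
#'
#' Categorical values are looked up in the entry's level map; numeric values
#' are linearly interpolated between the entry's anchor points (clamped to
#' the terminal anchors outside their range). Optimal values score 30, worst
#' values 0.
#'
#' @param value Raw predicted value (character level or numeric).
#' @param parameter Parameter name (must exist in the rubric).
#' @param rubric An `admet_rubric`.
#' @return Score in \[0, 30\].
#' @export
score_parameter <- function(value, parameter, rubric) {
  entry <- rubric[[parameter]]
  if (is.null(entry))
    stop("parameter not in rubric: ", parameter)
  if (!is.null(entry$map)) {
    sc <- entry$map[[as.character(value)]]
    if (is.null(sc))
      stop("value '", value, "' not a rubric level of ", parameter)
    as.numeric(sc)
  } else {
    v <- suppressWarnings(as.numeric(value))
    if (is.na(v)) stop("non-numeric value for numeric rubric entry ", parameter)
    stats::approx(unlist(entry$values), unlist(entry$scores), xout = v,
                  rule = 2)$y
  }
}

#' Score a full ADMET parameter table
#'
#' @param tab data.frame with columns `compound_id`, `parameter`, `value`.
#' @param rubric An `admet_rubric`.
#' @return The table with `category` and `score` columns appended.
#' @export
score_admet_table <- function(tab, rubric) {
  stopifnot(all(c("compound_id", "parameter", "value") %in% names(tab)))
  tab$category <- vapply(tab$parameter, function(p) {
    if (is.null(rubric[[p]])) stop("parameter not in rubric: ", p)
    rubric[[p]]$category
  }, character(1))
  tab$score <- mapply(score_parameter, tab$value, tab$parameter,
                      MoreArgs = list(rubric = rubric))
  tab
}

#' Weighted ADMET prediction score
#'
#' Per-category means of the 0-30 parameter scores are combined as a
#' weighted average: `score = sum(w_c * mean_c) / sum(w_c)` with default
#' weights (2, 3, 2, 1, 1) for physicochemical, pharmacokinetics,
#' drug-likeness, medicinal chemistry and bioavailability. The result lives
#' on the same 0 (poor) to 30 (optimal) scale; it attains 30 exactly when
#' every parameter is optimal and 0 when every parameter is at its worst.
#'
#' @param scored data.frame with columns `category` and `score` for a single
#'   compound (e.g. one compound's rows of [score_admet_table()]).
#' @param weights Named numeric category weights; every category in
#'   `names(weights)` must be populated.
#' @return list with `prediction_score` and `category_means` (named vector).
#' @export
prediction_score <- function(scored, weights = admet_categories()) {
  stopifnot(all(c("category", "score") %in% names(scored)))
  if (any(scored$score < 0 | scored$score > 30))
    stop("parameter scores must lie in [0, 30]")
  means <- vapply(names(weights), function(cat) {
    s <- scored$score[scored$category == cat]
    if (length(s) == 0L)
      stop("empty category: ", cat, " (cannot average)")
    mean(s)
  }, numeric(1))
  list(prediction_score = sum(weights * means) / sum(weights),
       category_means = means)
}

#' Select the working set by rank product of potency and prediction score
#'
#' Candidates are ranked by the product of their ascending-EC50 rank and
#' their descending-prediction-score rank (average ranks on ties); the `k`
#' best rank products form the working set. Rank-product ties are broken by
#' the lower EC50, then by compound id. Only active compounds are eligible.
#' With `method = "pareto"` the table instead gains a Pareto front index
#' (front 1 = not dominated on the EC50/score plane) and is ordered by
#' front, then rank product.
#'
#' @param tab data.frame with `compound_id`, `ec50`, `prediction_score` and
#'   (optionally) a logical `active` column; inactive rows are dropped.
#' @param k Working-set size (default 6).
#' @param method `"rank_product"` (default) or `"pareto"`.
#' @return The eligible table ordered by rank, with `rank_ec50`,
#'   `rank_score`, `rank_product`, `selected` (top `k`) and, for the Pareto
#'   method, `pareto_front`. Fewer than `k` eligible compounds triggers a
#'   warning and returns all.
#' @export
select_working_set <- function(tab, k = 6L,
                               method = c("rank_product", "pareto")) {
  method <- match.arg(method)
  stopifnot(all(c("compound_id", "ec50", "prediction_score") %in% names(tab)))
  if ("active" %in% names(tab)) tab <- tab[tab$active, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no eligible (active) compounds")
  tab$rank_ec50 <- rank(tab$ec50, ties.method = "average")
  tab$rank_score <- rank(-tab$prediction_score, ties.method = "average")
  tab$rank_product <- tab$rank_ec50 * tab$rank_score
  if (method == "pareto") {
    n <- nrow(tab)
    dominated_by <- function(i, j)  # j dominates i
      tab$ec50[j] <= tab$ec50[i] &&
      tab$prediction_score[j] >= tab$prediction_score[i] &&
      (tab$ec50[j] < tab$ec50[i] ||
         tab$prediction_score[j] > tab$prediction_score[i])
    front <- rep(NA_integer_, n)
    remaining <- seq_len(n)
    f <- 1L
    while (length(remaining)) {
      nd <- remaining[vapply(remaining, function(i)
        !any(vapply(remaining, dominated_by, logical(1), i = i)), logical(1))]
      front[nd] <- f
      remaining <- setdiff(remaining, nd)
      f <- f + 1L
    }
    tab$pareto_front <- front
    ord <- order(tab$pareto_front, tab$rank_product, tab$ec50,
                 tab$compound_id)
  } else {
    ord <- order(tab$rank_product, tab$ec50, tab$compound_id)
  }
  tab <- tab[ord, , drop = FALSE]
  if (nrow(tab) < k)
    warning("fewer than k = ", k, " eligible compounds; returning all")
  tab$selected <- seq_len(nrow(tab)) <= k
  rownames(tab) <- NULL
  tab
}

# ---- structures and fingerprints -------------------------------------------

#' Read molecules from an SDF (V2000) file
#'
#' Minimal reader of the MDL V2000 connection table: record name, atom block
#' (element symbols) and bond block (atom indices and bond order). Fixed
#' columns per the V2000 layout. Coordinates, charges and property blocks
#' are ignored; only the connectivity needed for path fingerprints is kept.
#'
#' @param path SDF file path (records separated by `$$$$`).
#' @return List of molecules: each a list with `name`, `atoms` (character
#'   vector of element symbols) and `bonds` (data.frame `a1`, `a2`,
#'   `order`). A malformed record raises an error naming its index.
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^\\${4}", lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  if (length(ends) == 0L) { starts <- 1L; ends <- length(lines) + 1L }
  mapply(function(s, e, idx) {
    rec <- lines[s:(e - 1L)]
    rec <- rec[cumsum(nzchar(trimws(rec)) | seq_along(rec) <= 4) > 0]
    if (length(rec) < 4L)
      stop("SDF record ", idx, ": truncated header")
    counts <- rec[4L]
    n_at <- suppressWarnings(as.integer(substr(counts, 1, 3)))
    n_bd <- suppressWarnings(as.integer(substr(counts, 4, 6)))
    if (is.na(n_at) || is.na(n_bd) || n_at < 1L)
      stop("SDF record ", idx, ": malformed counts line")
    if (length(rec) < 4L + n_at + n_bd)
      stop("SDF record ", idx, ": truncated atom/bond block")
    atom_lines <- rec[5:(4 + n_at)]
    atoms <- trimws(substr(atom_lines, 32, 34))
    if (any(atoms == ""))
      stop("SDF record ", idx, ": atom line missing element symbol")
    if (n_bd > 0L) {
      bond_lines <- rec[(5 + n_at):(4 + n_at + n_bd)]
      a1 <- as.integer(substr(bond_lines, 1, 3))
      a2 <- as.integer(substr(bond_lines, 4, 6))
      ord <- as.integer(substr(bond_lines, 7, 9))
      if (anyNA(a1) || anyNA(a2) || anyNA(ord) ||
          any(a1 < 1 | a1 > n_at | a2 < 1 | a2 > n_at))
        stop("SDF record ", idx, ": malformed bond block")
      bonds <- data.frame(a1 = a1, a2 = a2, order = ord)
    } else {
      bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
    }
    list(name = trimws(rec[1L]), atoms = atoms, bonds = bonds)
  }, starts, ends, seq_along(starts), SIMPLIFY = FALSE)
}

#' Hashed linear-path fingerprint of a molecule
#'
#' Enumerates all simple linear atom paths of 1 to `max_path` atoms in the
#' hydrogen-suppressed molecular graph, canonicalizes each path string
#' (lexicographic minimum of the forward and reverse walk over element
#' symbols and bond orders) and hashes it onto a fixed-length bit set. The
#' result is deterministic and invariant to atom numbering.
#'
#' @param mol A molecule as returned by [read_sdf()] (fields `atoms`,
#'   `bonds`).
#' @param nbits Fingerprint length in bits (default 1024).
#' @param max_path Maximum path length in atoms (default 7).
#' @return Object of class `fingerprint`: list with `bits` (sorted 0-based
#'   positions) and `length`.
#' @export
fingerprint <- function(mol, nbits = 1024L, max_path = 7L) {
  heavy <- which(mol$atoms != "H")
  relab <- match(seq_along(mol$atoms), heavy)
  elems <- mol$atoms[heavy]
  n <- length(heavy)
  adj <- vector("list", n)
  bonds <- mol$bonds
  if (nrow(bonds)) {
    keep <- !is.na(relab[bonds$a1]) & !is.na(relab[bonds$a2])
    bonds <- bonds[keep, , drop = FALSE]
    for (i in seq_len(nrow(bonds))) {
      u <- relab[bonds$a1[i]]; v <- relab[bonds$a2[i]]; o <- bonds$order[i]
      adj[[u]] <- rbind(adj[[u]], c(v, o))
      adj[[v]] <- rbind(adj[[v]], c(u, o))
    }
  }
  paths <- character(0)
  walk <- function(path, labels) {
    fwd <- paste(labels, collapse = "")
    rev_ <- paste(rev(labels), collapse = "")
    paths[[length(paths) + 1L]] <<- if (fwd <= rev_) fwd else rev_
    if (length(path) >= max_path) return()
    nb <- adj[[path[length(path)]]]
    if (is.null(nb)) return()
    for (i in seq_len(nrow(nb))) {
      v <- nb[i, 1]
      if (!(v %in% path))
        walk(c(path, v), c(labels, as.character(nb[i, 2]), elems[v]))
    }
  }
  for (a in seq_len(n)) walk(a, elems[a])
  bits <- sort(unique(vapply(unique(paths), hash_string, numeric(1),
                             modulus = nbits)))
  structure(list(bits = as.integer(bits), length = as.integer(nbits)),
            class = "fingerprint")
}

# deterministic polynomial string hash (31-bit), independent of locale
hash_string <- function(s, modulus) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  h %% modulus
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|` over set bits. Identical non-empty
#' fingerprints give 1; two empty fingerprints give 0 by convention.
#'
#' @param a,b `fingerprint` objects of equal length.
#' @return Coefficient in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$length != b$length) stop("fingerprint length mismatch")
  u <- length(union(a$bits, b$bits))
  if (u == 0L) return(0)
  length(intersect(a$bits, b$bits)) / u
}

#' Pairwise Tanimoto matrix over a compound set
#'
#' @param fps Named list of `fingerprint` objects.
#' @return Symmetric numeric matrix with unit diagonal for non-empty
#'   fingerprints.
#' @export
tanimoto_matrix <- function(fps) {
  n <- length(fps)
  m <- matrix(0, n, n, dimnames = list(names(fps), names(fps)))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    m[i, j] <- m[j, i] <- tanimoto(fps[[i]], fps[[j]])
  }
  m
}
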