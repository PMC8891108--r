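# Shared fixtures and independent reference implementations used as
# oracles across test files.

# --- V2000 SDF records built in code ----------------------------------------

sdf_atom_line <- function(elem, x = 0, y = 0, z = 0)
  sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
          x, y, z, elem)

sdf_bond_line <- function(a1, a2, order = 1L)
  sprintf("%3d%3d%3d  0", a1, a2, order)

sdf_record <- function(name, atoms, bonds) {
  c(name, "  test", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
            length(atoms), length(bonds)),
    vapply(seq_along(atoms), function(i)
      sdf_atom_line(atoms[i], x = i), character(1)),
    bonds,
    "M  END", "$$$$")
}

# ethanol heavy-atom skeleton C-C-O, atoms in two different orders
sdf_ethanol <- function() sdf_record("ethanol", c("C", "C", "O"),
                                     c(sdf_bond_line(1, 2),
                                       sdf_bond_line(2, 3)))
sdf_ethanol_permuted <- function() sdf_record("ethanol", c("O", "C", "C"),
                                              c(sdf_bond_line(3, 2),
                                                sdf_bond_line(2, 1)))
sdf_methane <- function() sdf_record("methane", "C", character())

write_sdf_fixture <- function(records) {
  path <- withr::local_tempfile(fileext = ".sdf",
                                .local_envir = parent.frame())
  writeLines(unlist(records), path)
  path
}

# --- step-up FDR procedures, written independently (O(m^2)) -----------------

brute_bh_adjust <- function(p) {
  m <- length(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    # adjusted p_i = min over j with p_j >= p_i of m * p_j / rank(p_j)
    cand <- vapply(seq_len(m), function(j) {
      rank_j <- sum(p <= p[j])
      m * p[j] / rank_j
    }, numeric(1))
    adj[i] <- min(1, min(cand[p >= p[i]]))
  }
  adj
}

brute_bh_reject <- function(p, level) {
  m <- length(p)
  k <- 0
  ps <- sort(p)
  for (i in seq_len(m)) if (ps[i] <= i / m * level) k <- i
  if (k == 0) rep(FALSE, m) else p <= ps[k]
}

brute_bky <- function(p, q) {
  m <- length(p)
  q1 <- q / (1 + q)
  s1 <- brute_bh_reject(p, q1)
  r1 <- sum(s1)
  if (r1 == 0) return(rep(FALSE, m))
  m0 <- m - r1
  if (m0 == 0) return(rep(TRUE, m))
  brute_bh_reject(p, q1 * m / m0)
}

# --- misc -------------------------------------------------------------------

# vector with exact sample mean and sd (for arithmetic QC oracles)
exact_moments <- function(x, mean, sd) {
  x <- as.numeric(scale(x))
  x * sd + mean
}
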