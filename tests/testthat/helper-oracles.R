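# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately naive (per-gene / per-string / brute-force)
# and never call the vectorised implementation paths they check.

LV <- c("up", "nc", "down")

# build a call_table whose cross-tabulation equals a given count matrix;
# counts: 3^k x 3 matrix, rownames = ":"-joined row-factor tuples in
# product order, colnames = up/nc/down
table_from_counts <- function(counts, row_factors, col_factor) {
  rows <- list()
  for (r in rownames(counts)) {
    for (cl in colnames(counts)) {
      n <- counts[r, cl]
      if (n > 0) {
        tup <- strsplit(r, ":", fixed = TRUE)[[1L]]
        rows[[paste(r, cl)]] <-
          matrix(rep(c(tup, cl), n), ncol = length(tup) + 1L, byrow = TRUE)
      }
    }
  }
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("g%06d", seq_len(nrow(m)))
  colnames(m) <- c(row_factors, col_factor)
  call_table(m)
}

# the nine observed counts printed in the two-treatment contingency
# table (inhibitor rows x hormone columns), cells summing to 20,566
table1_counts <- function() {
  matrix(c(89, 301, 3,
           365, 19197, 175,
           15, 280, 141),
         nrow = 3, byrow = TRUE, dimnames = list(LV, LV))
}

# the 27 observed counts of the three-treatment table (rows = EDE:U73
# tuples in product order), cells summing to 20,560
table2_counts <- function() {
  m <- matrix(c(
    60, 147, 1,     # up:up
    28, 131, 2,     # up:nc
    2, 4, 0,        # up:down
    119, 1238, 4,   # nc:up
    227, 16558, 89, # nc:nc
    14, 1401, 82,   # nc:down
    0, 2, 0,        # down:up
    8, 171, 30,     # down:nc
    5, 126, 111     # down:down
  ), nrow = 9, byrow = TRUE)
  rn <- as.vector(t(outer(LV, LV, paste, sep = ":")))
  dimnames(m) <- list(rn, LV)
  m
}

# scalar truth-table evaluation of the cluster predicates
oracle_cluster <- function(sa, x, wb, ws, d_excludes_inhibitor_up = TRUE,
                           c_excludes_w30sa_up = FALSE) {
  if (sa == "up") {
    if (x == "nc" && wb == "nc" && ws == "nc") return("none")
    if (ws == "down" && wb != "up" && x != "down") return("A")
    if (x == "up" && wb == "up" && ws != "down") return("B")
    return("none")
  }
  if (sa == "down") {
    if (x == "nc" && wb == "nc" && ws == "nc") return("none")
    if (ws == "up" && wb != "down" &&
        (!d_excludes_inhibitor_up || x != "up")) return("D")
    if (x == "down" && wb == "down" &&
        (!c_excludes_w30sa_up || ws != "up")) return("C")
    return("none")
  }
  "none"
}

# brute-force chi-squared over a contingency object's cells
oracle_chi2 <- function(observed, expected) {
  total <- 0
  for (i in seq_len(nrow(observed))) {
    for (j in seq_len(ncol(observed))) {
      if (expected[i, j] > 0)
        total <- total + (observed[i, j] - expected[i, j])^2 / expected[i, j]
    }
  }
  total
}

# naive per-string reverse complement
oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s)
    paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = ""), "",
    USE.NAMES = FALSE)
}

# naive double-strand presence count of one motif over a promoter set
oracle_presence <- function(motif, proms) {
  rc <- oracle_revcomp(motif)
  sum(vapply(unclass(proms)[seq_along(proms)], function(s)
    grepl(motif, s, fixed = TRUE) || grepl(rc, s, fixed = TRUE), TRUE))
}

# expand an IUPAC pattern into all literal strings (short patterns only)
oracle_iupac_expand <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T", M = "AC", R = "AG",
           W = "AT", S = "CG", Y = "CT", K = "GT", V = "ACG", H = "ACT",
           D = "AGT", B = "CGT", N = "ACGT")
  classes <- strsplit(map[strsplit(pattern, "")[[1L]]], "")
  grid <- do.call(expand.grid, c(classes, list(stringsAsFactors = FALSE)))
  apply(grid, 1L, paste, collapse = "")
}

# literal-expansion IUPAC match oracle: contains-or-contained, one strand
oracle_iupac_dir <- function(motif, pattern) {
  lits <- oracle_iupac_expand(pattern)
  any(vapply(lits, function(l)
    grepl(l, motif, fixed = TRUE) || grepl(motif, l, fixed = TRUE), TRUE))
}

random_call_matrix <- function(n_genes, contrasts, seed) {
  set.seed(seed)
  m <- matrix(sample(LV, n_genes * length(contrasts), replace = TRUE,
                     prob = c(0.1, 0.8, 0.1)),
              nrow = n_genes,
              dimnames = list(sprintf("g%05d", seq_len(n_genes)), contrasts))
  m
}
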