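mk_gene_table <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- c("SA", "EDE", "W30B", "W30SA")
  call_table(m)
}

test_that("worked call patterns land in the documented clusters", {
  tab <- mk_gene_table(
    c("up", "up", "up", "nc"),      # induced by inhibitor and W30 -> B
    c("up", "nc", "nc", "down"),    # SAW30-repressed -> A
    c("nc", "nc", "nc", "nc"),      # unaffected -> none
    c("down", "down", "down", "nc"),# repressed by inhibitor and W30 -> C
    c("down", "nc", "nc", "up"))    # SAW30-derepressed -> D
  a <- assign_clusters(tab, "EDE")
  expect_equal(unname(a$labels), c("B", "A", "none", "C", "D"))
  expect_match(a$audit[["g03"]], "not SA-responsive|unaffected")
})

test_that("exhaustive 81-pattern enumeration matches the predicate oracle", {
  pats <- expand.grid(SA = LV, EDE = LV, W30B = LV, W30SA = LV,
                      stringsAsFactors = FALSE)
  m <- as.matrix(pats)
  rownames(m) <- sprintf("p%03d", seq_len(nrow(m)))
  tab <- call_table(m)
  for (d_ex in c(TRUE, FALSE)) {
    for (c_guard in c(FALSE, TRUE)) {
      got <- assign_clusters(tab, "EDE", d_excludes_inhibitor_up = d_ex,
                             c_excludes_w30sa_up = c_guard)$labels
      want <- vapply(seq_len(nrow(pats)), function(i)
        oracle_cluster(pats$SA[i], pats$EDE[i], pats$W30B[i], pats$W30SA[i],
                       d_excludes_inhibitor_up = d_ex,
                       c_excludes_w30sa_up = c_guard), "")
      expect_identical(unname(got), want)
    }
  }
})

test_that("variant labels mark near-misses, never cluster members", {
  pats <- expand.grid(SA = LV, EDE = LV, W30B = LV, W30SA = LV,
                      stringsAsFactors = FALSE)
  m <- as.matrix(pats)
  rownames(m) <- sprintf("p%03d", seq_len(nrow(m)))
  a <- assign_clusters(call_table(m), "EDE")
  for (i in seq_len(nrow(pats))) {
    v <- a$variant_labels[[i]]
    lab <- a$labels[[i]]
    if (lab == "B") expect_false(any(c("B^X", "B^W30") %in% v))
    if (lab == "C") expect_false(any(c("C^X", "C^W30") %in% v))
    if ("B^X" %in% v) {
      # satisfies B except the basal W30 induction
      expect_true(pats$SA[i] == "up" && pats$EDE[i] == "up" &&
                  pats$W30B[i] != "up" && pats$W30SA[i] != "down")
    }
    if ("C^W30" %in% v) {
      expect_true(pats$SA[i] == "down" && pats$W30B[i] == "down" &&
                  pats$EDE[i] != "down")
    }
  }
  # exclusivity invariants: A/B and C/D never co-assigned (single label
  # by construction), and variant sets never contain the main label
  expect_true(all(a$labels %in% c("A", "B", "C", "D", "none")))
})

test_that("missing contrasts raise a configuration error listing them", {
  tab <- call_table(random_call_matrix(10, c("SA", "EDE"), 1))
  expect_error(assign_clusters(tab, "EDE"), "W30B")
})

test_that("reconcile: idempotence, set algebra, universe check", {
  tab <- call_table(random_call_matrix(500, c("SA", "EDE", "U73", "W30B",
                                              "W30SA"), 11))
  a1 <- assign_clusters(tab, "EDE")
  a2 <- assign_clusters(tab, "U73")
  rc <- reconcile(a1, a2)
  for (k in c("A", "B", "C", "D")) {
    s1 <- cluster_members(a1, k); s2 <- cluster_members(a2, k)
    expect_setequal(rc$stringent[[k]], intersect(s1, s2))
    expect_setequal(rc$loose[[k]], union(s1, s2))
    # monotonicity: stringent <= per-inhibitor <= loose
    expect_true(all(rc$stringent[[k]] %in% s1))
    expect_true(all(s1 %in% rc$loose[[k]]))
  }
  # identical assignments: stringent = loose = input
  rcc <- reconcile(a1, a1)
  for (k in c("A", "B", "C", "D")) {
    expect_setequal(rcc$stringent[[k]], cluster_members(a1, k))
    expect_setequal(rcc$loose[[k]], cluster_members(a1, k))
  }
  # differing universes rejected with the symmetric difference
  sub <- call_table(tab$calls[-1, , drop = FALSE])
  expect_error(reconcile(a1, assign_clusters(sub, "U73")),
               table_genes(tab)[1])
})

test_that("planted stringent/single membership is recovered exactly", {
  tab <- plant_clusters(sizes = c(A = 105, B = 39, C = 97, D = 23),
                        single_sizes = c(A = 16), n_background = 2000,
                        seed = 42)
  truth <- attr(tab, "truth")
  rc <- reconcile(assign_clusters(tab, "EDE"), assign_clusters(tab, "U73"))
  expect_length(rc$stringent$A, 105)
  expect_length(rc$loose$A, 121)
  expect_length(rc$stringent$B, 39)
  expect_length(rc$stringent$C, 97)
  expect_length(rc$stringent$D, 23)
  expect_setequal(rc$stringent$A,
                  truth$gene[truth$cluster == "A" & truth$mode == "stringent"])
  # loose-only members never appear in stringent
  singles <- truth$gene[truth$mode == "single"]
  expect_length(intersect(unlist(rc$stringent), singles), 0)
})

test_that("share arithmetic reproduces the printed percentages", {
  shares <- cluster_shares(c(A = 105, B = 39, C = 97, D = 23),
                           n_induced = 463, n_repressed = 319)
  expect_equal(unname(shares[c("A", "B", "D")]), c(23, 8, 7))
  expect_equal(unname(shares["C"]), 30)  # the paper prints 31; 97/319 = 30.4%
})

test_that("cluster modifier profile: closed form, null, empty cluster", {
  set.seed(5)
  n <- 10000
  calls <- random_call_matrix(n, c("SA", "EDE", "U73", "W30B", "W30SA"), 5)
  mod <- sample(c("up", "nc", "down"), n, replace = TRUE,
                prob = c(0.01, 0.98, 0.01))
  calls <- cbind(calls, R59 = mod)
  tab <- call_table(calls)
  a1 <- assign_clusters(tab, "EDE"); a2 <- assign_clusters(tab, "U73")
  rc <- reconcile(a1, a2)
  prof <- cluster_modifier_profile(rc, tab, "R59")
  # empty clusters are omitted, present rows delegate to the closed form
  nonempty <- names(Filter(length, rc$stringent))
  expect_setequal(unique(prof$cluster), nonempty)
  for (i in seq_len(nrow(prof))) {
    ref <- modifier_overrepresentation(rc$stringent[[prof$cluster[i]]],
                                       tab, "R59", prof$level[i])
    expect_equal(prof$fold[i], ref$fold)
  }
  # synthetic cluster with modifier=up for all members, fraction 0.01
  calls2 <- matrix("nc", 10000, 6,
                   dimnames = list(sprintf("x%05d", 1:10000),
                                   colnames(calls)))
  up_set <- sprintf("x%05d", 1:100)
  calls2[up_set, "R59"] <- "up"
  tab2 <- call_table(calls2)
  res <- modifier_overrepresentation(up_set[1:30], tab2, "R59", "up")
  expect_equal(res$fold, 100)
})
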