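test_that("two-treatment table reproduces printed marginals, expecteds, ratios", {
  tab <- table_from_counts(table1_counts(), "EDE", "SA")
  ct <- cross_tabulate(tab, "EDE", "SA")
  expect_equal(unname(ct$row_totals), c(393, 19737, 436))
  expect_equal(unname(ct$col_totals), c(469, 19778, 319))
  expect_equal(ct$grand_total, 20566)  # cell sum, not the printed total
  expect_equal(round(ct$expected["up", "nc"], 1), 377.9)
  expect_equal(round(ct$expected["nc", "nc"], 1), 18980.8)
  expect_equal(round(ct$expected["nc", "up"], 1), 450.1)
  expect_equal(round(ct$expected["nc", "down"], 1), 306.1)
  expect_equal(format_ratio(ct$ratio["up", "up"]), "10")
  expect_equal(format_ratio(ct$ratio["down", "down"]), "21")
  expect_equal(ct$ratio["up", "up"], 9.930576, tolerance = 1e-6)
  expect_equal(ct$ratio["down", "down"], 20.84931, tolerance = 1e-6)
})

test_that("contingency invariants hold on random tables", {
  for (seed in c(3, 17)) {
    tab <- call_table(random_call_matrix(2000, c("EDE", "U73", "SA"), seed))
    ct <- cross_tabulate(tab, c("EDE", "U73"), "SA")
    expect_equal(sum(ct$observed), ct$grand_total)
    expect_equal(unname(rowSums(ct$observed)), unname(ct$row_totals))
    expect_equal(unname(colSums(ct$observed)), unname(ct$col_totals))
    # marginal conservation of expected counts
    expect_equal(unname(rowSums(ct$expected)), unname(ct$row_totals),
                 tolerance = 1e-9)
    expect_equal(sum(ct$expected), ct$grand_total, tolerance = 1e-9)
    # ratio * expected = observed
    ok <- ct$expected > 0
    expect_equal(unname((ct$ratio * ct$expected)[ok]),
                 unname(ct$observed[ok]), tolerance = 1e-9)
    # chi2 equals the brute-force recomputation
    expect_equal(ct$chi2, oracle_chi2(ct$observed, ct$expected),
                 tolerance = 1e-9)
    expect_equal(ct$dof, 16L)
    # collapsing the 27-cell table over U73 reproduces the 9-cell table
    ct9 <- cross_tabulate(tab, "EDE", "SA")
    lv1 <- sub(":.*$", "", rownames(ct$observed))
    collapsed <- rowsum(ct$observed, lv1)[rownames(ct9$observed), ]
    expect_equal(unname(collapsed), unname(ct9$observed))
  }
})

test_that("independence fixed point gives ratio 1 and chi2 0", {
  # counts = exact outer product of marginals / N
  counts <- outer(c(up = 20, nc = 160, down = 20),
                  c(up = 30, nc = 140, down = 30)) / 200
  storage.mode(counts) <- "integer"  # outer product chosen to be integral
  tab <- table_from_counts(counts, "EDE", "SA")
  ct <- cross_tabulate(tab, "EDE", "SA")
  expect_equal(unname(ct$ratio), matrix(1, 3, 3), tolerance = 1e-12)
  expect_equal(ct$chi2, 0, tolerance = 1e-12)
})

test_that("enrichment_ratio arithmetic and guards", {
  expect_equal(enrichment_ratio(89, 393, 469, 20566), 9.930576,
               tolerance = 1e-6)
  expect_equal(enrichment_ratio(141, 436, 319, 20566), 20.84931,
               tolerance = 1e-5)
  expect_equal(enrichment_ratio(0, 10, 10, 100), 0)
  expect_true(is.na(enrichment_ratio(0, 0, 10, 100)))
  expect_error(enrichment_ratio(-1, 10, 10, 100), "non-negative")
  expect_error(enrichment_ratio(1, 10, 10, 0), "positive")
  expect_error(enrichment_ratio(1, 200, 10, 100), "exceed")
})

test_that("cross_tabulate rejects bad factor specifications", {
  tab <- call_table(random_call_matrix(50, c("EDE", "SA"), 1))
  expect_error(cross_tabulate(tab, "EDE", "EDE"), "disjoint")
  expect_error(cross_tabulate(tab, "NOPE", "SA"), "NOPE")
})

test_that("modifier over-representation: closed form and null behaviour", {
  set.seed(99)
  n <- 20000
  calls <- matrix("nc", n, 1, dimnames = list(sprintf("g%05d", 1:n), "R59"))
  up_genes <- sample(rownames(calls), 200)  # universe fraction 0.01
  calls[up_genes, 1] <- "up"
  tab <- call_table(calls)
  # cluster built entirely of modifier-up genes -> fold = 1 / fraction
  res <- modifier_overrepresentation(up_genes[1:40], tab, "R59", "up")
  expect_equal(res$fold, 100)
  # set = all universe genes with the call -> fold = |universe| / marginal
  res <- modifier_overrepresentation(up_genes, tab, "R59", "up")
  expect_equal(res$fold, n / 200)
  # random set -> fold ~ 1 within 3 SE of the binomial count
  rnd <- sample(rownames(calls), 5000)
  res <- modifier_overrepresentation(rnd, tab, "R59", "up")
  se <- sqrt(5000 * 0.01 * 0.99)
  expect_lt(abs(res$observed - res$expected), 3 * se)
  # errors and undefined flag
  expect_error(modifier_overrepresentation(character(0), tab, "R59", "up"),
               "empty")
  expect_true(is.na(
    modifier_overrepresentation(up_genes[1:5], tab, "R59", "down")$fold))
})

test_that("contingency TSV/JSON output round-trips the cells", {
  tab <- table_from_counts(table1_counts(), "EDE", "SA")
  ct <- cross_tabulate(tab, "EDE", "SA")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_contingency(ct, tsv)
  out <- read.delim(tsv)
  expect_equal(sum(out$observed), 20566)
  js <- jsonlite::read_json(sub("\\.tsv$", ".json", tsv),
                            simplifyVector = TRUE)
  expect_equal(js$grand_total, 20566)
  expect_equal(js$chi2, ct$chi2, tolerance = 1e-9)
})
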