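test_that("promoter extraction: coordinate arithmetic and truncation", {
  chr <- paste(rep("ACGT", 750), collapse = "")  # 3000 bp
  genome <- c(chr1 = chr)
  coords <- data.frame(
    gene = "gA", chrom = "chr1", strand = "+", tss = 2001,
    utr5_end = 2100, gene_end = 2500, stringsAsFactors = FALSE)
  ps <- extract_promoters(coords, genome)
  expect_equal(nchar(ps[["gA"]]), 1000)
  expect_equal(ps[["gA"]], substr(chr, 1001, 2000))
  # an upstream neighbour ending at 1500 truncates the window to 500 bp
  coords2 <- rbind(coords, data.frame(
    gene = "gB", chrom = "chr1", strand = "+", tss = 1200,
    utr5_end = 1300, gene_end = 1500, stringsAsFactors = FALSE))
  ps2 <- extract_promoters(coords2, genome)
  expect_equal(ps2[["gA"]], substr(chr, 1501, 2000))
  # errors
  bad <- coords; bad$tss <- 9999
  expect_error(extract_promoters(bad, genome), "outside")
  bad <- coords; bad$chrom <- "chrX"
  expect_error(extract_promoters(bad, genome), "unknown")
})

test_that("random annotations: extraction equals brute-force slice/revcomp", {
  set.seed(21)
  genome <- c(c1 = paste(sample(c("A", "C", "G", "T"), 5000, TRUE),
                         collapse = ""))
  n <- 12
  tss <- sort(sample(300:4700, n))
  strand <- sample(c("+", "-"), n, TRUE)
  coords <- data.frame(gene = sprintf("g%02d", 1:n), chrom = "c1",
                       strand = strand, tss = tss, utr5_end = tss,
                       gene_end = ifelse(strand == "+", pmin(tss + 150, 5000),
                                         pmax(tss - 150, 1)),
                       stringsAsFactors = FALSE)
  ps <- extract_promoters(coords, genome, max_len = 400)
  span <- cbind(pmin(coords$tss, coords$gene_end),
                pmax(coords$tss, coords$gene_end))
  for (i in seq_len(n)) {
    if (strand[i] == "+") {
      s <- max(1, tss[i] - 400); e <- tss[i] - 1
      for (j in setdiff(seq_len(n), i))
        if (span[j, 1] <= e && span[j, 2] >= s) s <- max(s, span[j, 2] + 1)
      want <- if (s <= e) substr(genome[["c1"]], s, e) else ""
    } else {
      s <- tss[i] + 1; e <- min(5000, tss[i] + 400)
      for (j in setdiff(seq_len(n), i))
        if (span[j, 1] <= e && span[j, 2] >= s) e <- min(e, span[j, 1] - 1)
      want <- if (s <= e) oracle_revcomp(substr(genome[["c1"]], s, e)) else ""
    }
    expect_identical(ps[[coords$gene[i]]], want)
  }
})

test_that("planted motif is detected far below the threshold", {
  sim <- simulate_promoters(100, 100, length = 500, motif = "TTGACC",
                            fg_presence = 0.5, bg_presence = 0.01, seed = 11)
  hits <- scan_motifs(sim$fg, sim$bg, kmin = 4, kmax = 8)
  expect_true(canonical_motif("TTGACC") %in% hits$motif)
  p <- hits$p_value[hits$motif == canonical_motif("TTGACC")]
  expect_lt(p, 1e-6)  # far below the 1e-5 retention threshold
  # chi-squared of the spec's planted 2x2 table (50,50,1,99), checked
  # against a brute-force statistic
  tab <- matrix(c(50, 50, 1, 99), 2, byrow = TRUE)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- oracle_chi2(tab, exp_tab)
  expect_equal(chi2, 63.19, tolerance = 1e-3)
  expect_lt(pchisq(chi2, 1, lower.tail = FALSE), 1e-14)
})

test_that("fg = bg yields no hits; lowering alpha never adds hits", {
  sim <- simulate_promoters(40, 40, length = 300, seed = 13)
  expect_equal(nrow(scan_motifs(sim$fg, sim$fg, kmax = 6)), 0)
  h5 <- scan_motifs(sim$fg, sim$bg, kmax = 6, alpha = 1e-2)
  h8 <- scan_motifs(sim$fg, sim$bg, kmax = 6, alpha = 1e-8)
  expect_true(all(h8$motif %in% h5$motif))
  expect_error(scan_motifs(sim$fg, sim$bg, alpha = 2), "alpha")
  expect_error(scan_motifs(sim$fg, sim$bg, kmin = 8, kmax = 4), "kmin")
})

test_that("presence counts equal the naive double-strand oracle", {
  sim <- simulate_promoters(30, 30, length = 200, motif = "ACGTAG",
                            fg_presence = 0.6, bg_presence = 0.05, seed = 17)
  hits <- scan_motifs(sim$fg, sim$bg, kmin = 4, kmax = 6, alpha = 0.05)
  pick <- hits[sample.int(nrow(hits), min(25, nrow(hits))), ]
  for (i in seq_len(nrow(pick))) {
    expect_equal(pick$fg_present[i], oracle_presence(pick$motif[i], sim$fg),
                 info = pick$motif[i])
    expect_equal(pick$bg_present[i], oracle_presence(pick$motif[i], sim$bg),
                 info = pick$motif[i])
    expect_equal(pick$fg_present[i] + pick$fg_absent[i], length(sim$fg))
  }
})

test_that("canonicalisation: reverse-complemented input gives the same hits", {
  sim <- simulate_promoters(30, 30, length = 200, motif = "TTGACC",
                            fg_presence = 0.7, bg_presence = 0, seed = 19)
  h1 <- scan_motifs(sim$fg, sim$bg, kmin = 5, kmax = 6, alpha = 1e-3)
  rc_fg <- promoter_set(setNames(oracle_revcomp(as.character(sim$fg)),
                                 names(sim$fg)))
  rc_bg <- promoter_set(setNames(oracle_revcomp(as.character(sim$bg)),
                                 names(sim$bg)))
  h2 <- scan_motifs(rc_fg, rc_bg, kmin = 5, kmax = 6, alpha = 1e-3)
  expect_identical(h1$motif, h2$motif)
  expect_identical(h1$fg_present, h2$fg_present)
  # every reported motif is canonical
  expect_identical(h1$motif, canonical_motif(h1$motif))
})

test_that("IUPAC matching agrees with literal expansion; examples hold", {
  expect_identical(iupac_match("TTGACC", "TTGACY"), "forward")
  expect_identical(iupac_match("GGTCAA", "TTGACY"), "reverse")
  expect_true(is.na(iupac_match("GGTACA", "TTGACY")))
  expect_error(iupac_match("ACGT", "AXGT"), "IUPAC")
  set.seed(23)
  for (rep in 1:40) {
    motif <- paste(sample(c("A", "C", "G", "T"), sample(4:7, 1), TRUE),
                   collapse = "")
    pattern <- paste(sample(c("A", "C", "G", "T", "M", "Y", "R", "W", "S",
                              "K", "N"), sample(4:6, 1), TRUE), collapse = "")
    want_f <- oracle_iupac_dir(motif, pattern)
    want_r <- oracle_iupac_dir(oracle_revcomp(motif), pattern)
    got <- iupac_match(motif, pattern)
    want <- if (want_f && want_r) "both" else if (want_f) "forward"
            else if (want_r) "reverse" else NA_character_
    expect_identical(got, want, info = paste(motif, pattern))
  }
})

test_that("catalog annotation and nested-hit pruning", {
  sim <- simulate_promoters(60, 60, length = 300, motif = "TTGACCA",
                            fg_presence = 0.8, bg_presence = 0, seed = 29)
  hits <- scan_motifs(sim$fg, sim$bg, kmin = 5, kmax = 7)
  catalog <- data.frame(name = c("WBOX", "TBOX"),
                        pattern = c("TTGACY", "ACTTTG"),
                        stringsAsFactors = FALSE)
  ann <- match_catalog(hits, catalog)
  planted <- ann[ann$motif == canonical_motif("TTGACCA"), ]
  expect_equal(nrow(planted), 1)
  expect_match(planted$catalog_match, "WBOX")
  # sub-motifs of the planted 7-mer are significant too; pruning keeps
  # one hit per containment chain
  pruned <- prune_nested(hits)
  expect_lte(nrow(pruned), nrow(hits))
  contains_either <- function(long, short)
    grepl(short, long, fixed = TRUE) ||
      grepl(oracle_revcomp(short), long, fixed = TRUE)
  for (i in seq_len(nrow(pruned))) {
    for (j in seq_len(nrow(pruned))) {
      if (i == j) next
      mi <- pruned$motif[i]; mj <- pruned$motif[j]
      if (nchar(mi) < nchar(mj))
        expect_false(contains_either(mj, mi))
    }
  }
})

test_that("promoter sets validate and round-trip through FASTA", {
  expect_error(promoter_set(c(a = "ACGT", a = "ACGT")), "duplicate")
  expect_error(promoter_set(c(a = "ACGU")), "non-ACGTN")
  ps <- promoter_set(c(g1 = "ACGTN", g2 = "acgtacgt", g3 = "ACG"))
  expect_identical(ps[["g2"]], "ACGTACGT")
  expect_identical(unname(attr(ps, "usable")), c(TRUE, TRUE, FALSE))
  f <- withr::local_tempfile(fileext = ".fa")
  write_promoters(ps, f)
  back <- read_promoters(f)
  expect_identical(as.character(back), as.character(ps))
})
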