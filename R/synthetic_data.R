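#' Independence cell probabilities from trinary marginals
#'
#' Builds the joint probability vector over the 3^k x 3 response-mode
#' cells implied by independent row-factor and column-factor marginals;
#' optional per-cell multipliers are applied to the independence product
#' and the result renormalised, which plants known observed/expected
#' ratios.
#'
#' @param row_marginals List of named numeric vectors (one per row
#'   factor, names `up`, `nc`, `down`), each summing to 1.
#' @param col_marginal Named numeric vector over `up/nc/down`.
#' @param multipliers Optional numeric vector over the cells in
#'   row-major product order (rows = level tuples of the row factors in
#'   up > nc > down product order, columns up/nc/down), or a matrix of
#'   that shape.
#' @return Named numeric cell-probability vector (names
#'   `"rowlev1[:rowlev2]|collev"`), summing to 1, with attribute
#'   `planted_ratio` giving each cell's probability ratio to the implied
#'   independence product (the expected observed/expected ratio).
#' @export
independence_probs <- function(row_marginals, col_marginal,
                               multipliers = NULL) {
  if (!is.list(row_marginals)) row_marginals <- list(row_marginals)
  lv <- call_levels()
  k <- length(row_marginals)
  grid <- .level_grid(k)
  rown <- apply(grid, 1L, paste, collapse = ":")
  rowp <- apply(grid, 1L, function(tuple)
    prod(vapply(seq_len(k), function(j) row_marginals[[j]][[tuple[j]]], 0)))
  probs <- outer(rowp, col_marginal[lv])
  dimnames(probs) <- list(rown, lv)
  if (!is.null(multipliers)) {
    probs <- probs * as.numeric(multipliers)
    probs <- probs / sum(probs)
  }
  probs <- probs / sum(probs)
  # ratio of final cell prob to the independence product of ITS OWN
  # marginals (what cross_tabulate estimates)
  rm2 <- rowSums(probs); cm2 <- colSums(probs)
  ratio <- probs / outer(rm2, cm2)
  out <- stats::setNames(as.vector(probs),
                         as.vector(outer(rown, lv, paste, sep = "|")))
  attr(out, "planted_ratio") <- stats::setNames(
    as.vector(ratio), names(out))
  out
}

#' Simulate a call table from planted cell probabilities
#'
#' Assigns genes to response-mode cells by a seeded multinomial draw, so
#' that [cross_tabulate()] recovers the planted observed/expected ratios
#' up to sampling error.
#'
#' @param n_genes Number of genes.
#' @param factors Character vector of contrast names; the last one is
#'   the column factor, the others the row factors.
#' @param cell_probs Named cell-probability vector as returned by
#'   [independence_probs()] (names `"rowtuple|collev"`), or any named
#'   vector over the full cell grid; renormalised if needed.
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @return A [call_table()] with attribute `truth` recording the planted
#'   cell probabilities and implied ratios.
#' @export
simulate_call_table <- function(n_genes, factors, cell_probs, seed) {
  k <- length(factors) - 1L
  if (k < 1L) stop("need >= 2 factors (>= 1 row factor + 1 column factor)")
  lv <- call_levels()
  grid <- .level_grid(k)
  rown <- apply(grid, 1L, paste, collapse = ":")
  cells <- as.vector(outer(rown, lv, paste, sep = "|"))
  if (is.null(names(cell_probs)) || !setequal(names(cell_probs), cells))
    stop("cell_probs must be named over the full cell grid")
  p <- cell_probs[cells]
  if (any(p < 0)) stop("negative cell probability")
  p <- p / sum(p)
  set.seed(seed)
  draw <- sample(cells, n_genes, replace = TRUE, prob = p)
  parts <- strsplit(draw, "|", fixed = TRUE)
  rowlev <- strsplit(vapply(parts, `[[`, "", 1L), ":", fixed = TRUE)
  calls <- matrix("nc", nrow = n_genes, ncol = length(factors),
                  dimnames = list(sprintf("g%05d", seq_len(n_genes)), factors))
  for (j in seq_len(k)) calls[, j] <- vapply(rowlev, `[[`, "", j)
  calls[, k + 1L] <- vapply(parts, `[[`, "", 2L)
  out <- call_table(calls, provenance = sprintf("simulated (seed %d)", seed))
  attr(out, "truth") <- list(cell_probs = stats::setNames(as.vector(p), cells),
                             planted_ratio = attr(cell_probs, "planted_ratio"))
  out
}

# all 3^n call patterns over `contrasts`, as a character matrix
.all_patterns <- function(contrasts) {
  grid <- .level_grid(length(contrasts))
  m <- as.matrix(grid)
  colnames(m) <- contrasts
  rownames(m) <- apply(m, 1L, paste, collapse = ":")
  m
}

#' Plant genes satisfying the cluster predicates
#'
#' Generates a call table over the contrasts `SA`, two inhibitors,
#' `W30B` and `W30SA` in which a requested number of genes satisfies
#' each cluster's predicate — under both inhibitors (stringent members),
#' or under exactly one (loose-only members) — and background genes
#' satisfy no cluster predicate under either inhibitor. Patterns are
#' sampled uniformly over each predicate's satisfying set so all rule
#' branches are exercised; background patterns are rejection-sampled
#' against all cluster predicates so specificity 1.0 is attainable.
#'
#' @param sizes Named vector over `A`,`B`,`C`,`D`: stringent member
#'   counts (satisfying under both inhibitors).
#' @param single_sizes Named vector over `A`,`B`,`C`,`D`: loose-only
#'   member counts (satisfying under exactly one inhibitor, the first by
#'   convention).
#' @param n_background Background gene count.
#' @param inhibitors Two inhibitor contrast names, default
#'   `c("EDE", "U73")`.
#' @param seed Integer RNG seed.
#' @param ... Rule switches passed to [assign_clusters()].
#' @return A [call_table()] with attribute `truth`: data.frame `gene`,
#'   `cluster` (`none` for background), `mode`
#'   (`stringent`/`single`/`background`).
#' @export
plant_clusters <- function(sizes = c(A = 0, B = 0, C = 0, D = 0),
                           single_sizes = c(A = 0, B = 0, C = 0, D = 0),
                           n_background = 0,
                           inhibitors = c("EDE", "U73"), seed = 1, ...) {
  stopifnot(length(inhibitors) == 2L)
  norm_sizes <- function(x) {
    out <- c(A = 0, B = 0, C = 0, D = 0)
    out[names(x)] <- x
    out
  }
  sizes <- norm_sizes(sizes)
  single_sizes <- norm_sizes(single_sizes)
  contrasts <- c("SA", inhibitors, "W30B", "W30SA")
  pats <- .all_patterns(contrasts)
  ref <- call_table(pats)
  lab1 <- assign_clusters(ref, inhibitors[1L], ...)$labels
  lab2 <- assign_clusters(ref, inhibitors[2L], ...)$labels
  cl <- c("A", "B", "C", "D")
  for (k in cl) {
    if ((sizes[k] > 0 && !any(lab1 == k & lab2 == k)) ||
        (single_sizes[k] > 0 && !any(lab1 == k & lab2 != k)))
      stop("no satisfying pattern for cluster ", k)  # guarded; unreachable
  }
  set.seed(seed)
  rows <- character(0); truth <- list()
  add <- function(pool, n, cluster, mode) {
    if (n == 0) return()
    pick <- sample(pool, n, replace = TRUE)
    rows <<- c(rows, pick)
    truth[[length(truth) + 1L]] <<- data.frame(
      cluster = cluster, mode = mode, pattern = pick,
      stringsAsFactors = FALSE)
  }
  for (k in cl) {
    add(rownames(pats)[lab1 == k & lab2 == k], sizes[k], k, "stringent")
    add(rownames(pats)[lab1 == k & lab2 != k], single_sizes[k], k, "single")
  }
  add(rownames(pats)[lab1 == "none" & lab2 == "none"], n_background,
      "none", "background")
  truth <- do.call(rbind, truth)
  genes <- sprintf("g%05d", seq_along(rows))
  calls <- pats[rows, , drop = FALSE]
  rownames(calls) <- genes
  truth$gene <- genes
  out <- call_table(calls, provenance = sprintf("planted clusters (seed %d)",
                                                seed))
  attr(out, "truth") <- truth[, c("gene", "cluster", "mode", "pattern")]
  out
}

# i.i.d. promoter sequence at a given GC fraction
.random_seq <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate foreground/background promoter sets with a planted motif
#'
#' Background composition is i.i.d. at the stated GC fraction; with the
#' stated per-set presence probability a promoter receives one planted
#' motif insertion (overwriting the background) at a uniform position,
#' on a uniformly chosen strand.
#'
#' @param n_fg,n_bg Set sizes.
#' @param length Promoter length in bp (default 500).
#' @param gc GC fraction (default 0.36, A. thaliana-like intergenic).
#' @param motif Planted motif (4-10 bp over ACGT), or `NULL` for pure
#'   background.
#' @param fg_presence,bg_presence Per-promoter insertion probabilities.
#' @param seed Integer RNG seed.
#' @return List `fg`, `bg` ([promoter_set()]s) and `truth` (data.frame
#'   `set`, `gene`, `carrier`, `position`, `strand`).
#' @export
simulate_promoters <- function(n_fg, n_bg, length = 500, gc = 0.36,
                               motif = NULL, fg_presence = 0, bg_presence = 0,
                               seed = 1) {
  if (!is.null(motif)) {
    if (nchar(motif) > length) stop("motif longer than promoter")
    if (grepl("[^ACGT]", motif)) stop("motif must be plain ACGT")
  }
  stopifnot(fg_presence >= 0, fg_presence <= 1,
            bg_presence >= 0, bg_presence <= 1)
  set.seed(seed)
  gen_set <- function(n, presence, prefix) {
    seqs <- character(n); truth <- vector("list", n)
    for (i in seq_len(n)) {
      s <- .random_seq(length, gc)
      carrier <- !is.null(motif) && stats::runif(1) < presence
      pos <- NA_integer_; strand <- NA_character_
      if (carrier) {
        ins <- if (stats::runif(1) < 0.5) motif else revcomp(motif)
        strand <- if (ins == motif) "+" else "-"
        pos <- sample.int(length - nchar(motif) + 1L, 1L)
        substr(s, pos, pos + nchar(motif) - 1L) <- ins
      }
      seqs[i] <- s
      truth[[i]] <- data.frame(set = prefix,
                               gene = sprintf("%s%04d", prefix, i),
                               carrier = carrier, position = pos,
                               strand = strand, stringsAsFactors = FALSE)
    }
    names(seqs) <- sprintf("%s%04d", prefix, seq_len(n))
    list(ps = promoter_set(seqs), truth = do.call(rbind, truth))
  }
  fg <- gen_set(n_fg, fg_presence, "fg")
  bg <- gen_set(n_bg, bg_presence, "bg")
  list(fg = fg$ps, bg = bg$ps, truth = rbind(fg$truth, bg$truth))
}

#' Simulate an annotation map with planted category enrichment
#'
#' Each gene-category annotation is an independent Bernoulli draw at the
#' category's background frequency; for members of the enriched set the
#' probability is multiplied by the planted enrichment factor (capped at
#' 1), so [enrichment()] recovers the factor up to sampling error.
#'
#' @param universe Character vector of gene IDs.
#' @param set Character vector, subset of `universe`, receiving the
#'   planted enrichment.
#' @param bg_freq Named numeric vector of per-category background
#'   annotation frequencies.
#' @param enrich Named numeric vector (same names) of planted
#'   set-enrichment factors; default 1 (no enrichment).
#' @param seed Integer RNG seed.
#' @return An [annotation_map()] with attribute `truth` = list of the
#'   planted frequencies and factors.
#' @export
simulate_annotations <- function(universe, set = character(0), bg_freq,
                                 enrich = NULL, seed = 1) {
  if (is.null(names(bg_freq))) stop("bg_freq must be named by category")
  if (is.null(enrich)) enrich <- stats::setNames(rep(1, length(bg_freq)),
                                                 names(bg_freq))
  stopifnot(all(bg_freq >= 0 & bg_freq <= 1), all(enrich >= 0),
            all(set %in% universe))
  set.seed(seed)
  gene <- character(0); category <- character(0)
  in_set <- universe %in% set
  for (cat in names(bg_freq)) {
    p <- ifelse(in_set, pmin(1, bg_freq[[cat]] * enrich[[cat]]),
                bg_freq[[cat]])
    hit <- stats::runif(length(universe)) < p
    gene <- c(gene, universe[hit])
    category <- c(category, rep(cat, sum(hit)))
  }
  ann <- annotation_map(gene, category, universe)
  attr(ann, "truth") <- list(bg_freq = bg_freq, enrich = enrich)
  ann
}

#' Simulate an experiment panel with a planted similarity gradient
#'
#' Experiments are noisy copies of the signature with i.i.d. Gaussian
#' noise whose SD increases along the panel, so the true similarity
#' ranking is the panel order.
#'
#' @param sig A [build_signature()] object.
#' @param n_experiments Panel size.
#' @param noise_sd Numeric vector of per-experiment noise SDs
#'   (recycled/ascending by default: `seq(0, 2, length.out = n)` times
#'   the SD of the signature values).
#' @param seed Integer RNG seed.
#' @return Numeric matrix (genes x experiments, colnames `exp01`...)
#'   with attribute `truth` = the noise SDs (true rank = ascending
#'   order).
#' @export
simulate_panel <- function(sig, n_experiments, noise_sd = NULL, seed = 1) {
  stopifnot(is.data.frame(sig), n_experiments >= 1)
  if (is.null(noise_sd))
    noise_sd <- seq(0, 2, length.out = n_experiments) * stats::sd(sig$change)
  stopifnot(length(noise_sd) == n_experiments)
  set.seed(seed)
  panel <- vapply(seq_len(n_experiments), function(i)
    sig$change + stats::rnorm(nrow(sig), 0, noise_sd[i]),
    numeric(nrow(sig)))
  rownames(panel) <- sig$gene
  colnames(panel) <- sprintf("exp%02d", seq_len(n_experiments))
  attr(panel, "truth") <- noise_sd
  panel
}
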