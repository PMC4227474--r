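#' Observed/expected enrichment ratio for one contingency cell
#'
#' Ratio of an observed cell count to the count expected under
#' independence of the row and column classifications,
#' `observed * grand_total / (row_total * col_total)`.
#'
#' @param observed,row_total,col_total,grand_total Non-negative counts;
#'   `grand_total > 0` and `row_total, col_total <= grand_total`.
#' @return The ratio, or `NA_real_` (undefined) when
#'   `row_total * col_total == 0`.
#' @export
enrichment_ratio <- function(observed, row_total, col_total, grand_total) {
  if (any(c(observed, row_total, col_total, grand_total) < 0))
    stop("counts must be non-negative")
  if (grand_total <= 0) stop("grand_total must be positive")
  if (any(row_total > grand_total) || any(col_total > grand_total))
    stop("marginal totals cannot exceed the grand total")
  denom <- row_total * col_total
  ifelse(denom == 0, NA_real_, observed * grand_total / denom)
}

#' Display rounding for enrichment ratios
#'
#' Ratios are reported rounded half-up to one decimal, and to the nearest
#' integer once they reach 10; full precision is always retained
#' internally, this helper affects display only.
#'
#' @param x Numeric vector of ratios.
#' @return Character vector of display values.
#' @export
format_ratio <- function(x) {
  half_up <- function(v, digits) {
    p <- 10^digits
    floor(v * p + 0.5) / p
  }
  ifelse(is.na(x), NA_character_,
         ifelse(half_up(x, 0) >= 10, sprintf("%d", as.integer(half_up(x, 0))),
                sprintf("%.1f", half_up(x, 1))))
}

# ordered level tuples for k row factors: lexicographic product order,
# up before nc before down, first factor slowest -- mirrors the printed
# table layout
.level_grid <- function(k) {
  lv <- call_levels()
  grid <- do.call(expand.grid,
                  c(rep(list(lv), k), list(stringsAsFactors = FALSE)))
  grid <- grid[do.call(order, lapply(grid, function(col) match(col, lv))), ,
               drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Cross-tabulate trinary response modes
#'
#' Counts genes into the Cartesian product of trinary levels over one or
#' more row factors against one column factor (3^k x 3 cells), computes
#' independence-expected counts `E = row_total * col_total / N`,
#' observed/expected ratios, and the chi-squared statistic
#' `sum (O - E)^2 / E` over cells with `E > 0` (no continuity
#' correction; skipped cells are reported). The grand total is always the
#' sum of observed cells. The universe is the set of genes with calls for
#' all named contrasts, i.e. all genes of the table (call tables are
#' complete by construction).
#'
#' @param table A [call_table()].
#' @param row_factors Character vector of 1..k contrast names.
#' @param col_factor A single contrast name, disjoint from `row_factors`.
#' @return An object of class `contingency` with components `observed`,
#'   `expected`, `ratio` (matrices, rows named by `:`-joined level
#'   tuples), `row_levels` (data.frame of level tuples), `col_levels`,
#'   `row_factors`, `col_factor`, `row_totals`, `col_totals`,
#'   `grand_total`, `chi2`, `dof`, `p_value`, `skipped_cells`.
#' @export
cross_tabulate <- function(table, row_factors, col_factor) {
  stopifnot(inherits(table, "call_table"), length(col_factor) == 1L)
  .require_contrasts(table, c(row_factors, col_factor))
  if (col_factor %in% row_factors)
    stop("row_factors must be disjoint from col_factor")
  n <- nrow(table$calls)
  if (n == 0L) stop("empty gene universe")
  k <- length(row_factors)
  lv <- call_levels()
  grid <- .level_grid(k)
  row_names <- apply(grid, 1L, paste, collapse = ":")
  row_key <- apply(table$calls[, row_factors, drop = FALSE], 1L,
                   paste, collapse = ":")
  observed <- matrix(0L, nrow = 3L^k, ncol = 3L,
                     dimnames = list(row_names, lv))
  tab <- table(factor(row_key, levels = row_names),
               factor(table$calls[, col_factor], levels = lv))
  observed[] <- as.integer(tab)
  row_totals <- rowSums(observed)
  col_totals <- colSums(observed)
  grand <- sum(observed)
  expected <- outer(row_totals, col_totals) / grand
  ratio <- ifelse(expected > 0, observed / expected, NA_real_)
  keep <- expected > 0
  chi2 <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  dof <- (nrow(observed) - 1L) * (ncol(observed) - 1L)
  structure(list(
    observed = observed, expected = expected, ratio = ratio,
    row_levels = grid, col_levels = lv,
    row_factors = row_factors, col_factor = col_factor,
    row_totals = row_totals, col_totals = col_totals,
    grand_total = grand,
    chi2 = chi2, dof = dof,
    p_value = stats::pchisq(chi2, dof, lower.tail = FALSE),
    skipped_cells = sum(!keep)
  ), class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  cat(sprintf("contingency: [%s] x %s, N = %d\n",
              paste(x$row_factors, collapse = ","), x$col_factor,
              x$grand_total))
  disp <- matrix(sprintf("%d (%.1f) %s", x$observed,
                         x$expected, format_ratio(x$ratio)),
                 nrow = nrow(x$observed), dimnames = dimnames(x$observed))
  print(disp, quote = FALSE)
  cat(sprintf("chi2 = %.4g, dof = %d, p = %.3g\n", x$chi2, x$dof, x$p_value))
  invisible(x)
}

#' Write a contingency result to TSV with a JSON sidecar
#'
#' One TSV row per cell (level tuple, observed, expected, ratio); the
#' sidecar carries chi2, dof, p-value and the totals.
#'
#' @param x A `contingency` object.
#' @param tsv_path Output TSV path.
#' @param json_path Output JSON path; default replaces the extension.
#' @return `tsv_path`, invisibly.
#' @export
write_contingency <- function(x, tsv_path,
                              json_path = sub("\\.tsv$", ".json", tsv_path)) {
  stopifnot(inherits(x, "contingency"))
  rows <- expand.grid(row = rownames(x$observed), col = colnames(x$observed),
                      stringsAsFactors = FALSE)
  dt <- data.table::data.table(
    row_levels = rows$row, col_level = rows$col,
    observed = as.vector(x$observed[cbind(rows$row, rows$col)]),
    expected = as.vector(x$expected[cbind(rows$row, rows$col)]),
    ratio = as.vector(x$ratio[cbind(rows$row, rows$col)]))
  data.table::fwrite(dt, tsv_path, sep = "\t", quote = FALSE)
  jsonlite::write_json(list(
    row_factors = x$row_factors, col_factor = x$col_factor,
    chi2 = x$chi2, dof = x$dof, p_value = x$p_value,
    row_totals = as.list(x$row_totals), col_totals = as.list(x$col_totals),
    grand_total = x$grand_total, skipped_cells = x$skipped_cells
  ), json_path, auto_unbox = TRUE, digits = NA)
  invisible(tsv_path)
}

#' Fold over-representation of a modifier response within a gene set
#'
#' Compares the frequency of a given call level on a modifier contrast
#' within a gene set to its genome-wide (universe) frequency:
#' `fold = (set members with call == level on modifier) /
#' (|set| * universe_fraction)`.
#'
#' @param gene_set Character vector of gene IDs, subset of the table
#'   universe.
#' @param table A [call_table()] containing the modifier contrast.
#' @param modifier Contrast name.
#' @param level One of `up`, `nc`, `down`.
#' @return Named list with `observed`, `expected`, `fold` (fold is
#'   `NA_real_` when the universe marginal for `level` is zero).
#' @export
modifier_overrepresentation <- function(gene_set, table, modifier, level) {
  stopifnot(inherits(table, "call_table"))
  .require_contrasts(table, modifier)
  level <- match.arg(level, call_levels())
  if (length(gene_set) == 0L) stop("empty gene_set")
  outside <- setdiff(gene_set, table_genes(table))
  if (length(outside))
    stop("gene_set members outside the table universe: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  calls <- table$calls[, modifier]
  marginal <- sum(calls == level)
  observed <- sum(calls[gene_set] == level)
  if (marginal == 0L)
    return(list(observed = observed, expected = 0, fold = NA_real_))
  genome_fraction <- marginal / nrow(table$calls)
  expected <- length(gene_set) * genome_fraction
  list(observed = observed, expected = expected, fold = observed / expected)
}
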