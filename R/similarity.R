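#' Build an expression-change signature
#'
#' A signature is the `n_top` most up-regulated plus the `n_top` most
#' down-regulated genes of an experiment, carried with their signed
#' change values, as used for transcriptome similarity searches against
#' an experiment compendium. Ties are broken by gene ID lexicographic
#' order so the selection is deterministic.
#'
#' @param changes Named numeric vector, gene -> signed change value;
#'   at least `2 * n_top` finite values required.
#' @param n_top Number of genes kept at each extreme (default 200).
#' @param direction_only If `TRUE`, signature values are collapsed to
#'   `+1`/`-1` (call-level signature mode).
#' @return Object of class `signature`: data.frame `gene`, `change`
#'   sorted by change descending, with attributes `n_up`, `n_down`.
#' @export
build_signature <- function(changes, n_top = 200, direction_only = FALSE) {
  changes <- changes[is.finite(changes)]
  if (length(changes) < 2 * n_top)
    stop(sprintf("need >= %d genes with finite changes, got %d",
                 2 * n_top, length(changes)))
  ord <- order(-changes, names(changes))
  up <- ord[seq_len(n_top)]
  down <- rev(ord)[seq_len(n_top)]
  down <- down[order(changes[down], names(changes)[down])]
  if (any(changes[up] <= 0) || any(changes[down] >= 0))
    warning("signature extremes include non-positive 'up' or ",
            "non-negative 'down' changes (heavy ties or one-sided input)")
  sel <- c(up, rev(down))
  vals <- unname(changes[sel])
  if (direction_only) vals <- c(rep(1, n_top), rep(-1, n_top))
  out <- data.frame(gene = names(changes)[sel], change = vals,
                    stringsAsFactors = FALSE)
  attr(out, "n_up") <- n_top
  attr(out, "n_down") <- n_top
  class(out) <- c("signature", "data.frame")
  out
}

#' Rank an experiment panel against a signature
#'
#' For each experiment the Euclidean distance to the signature is taken
#' over the genes shared between the two, normalised by `sqrt(n_shared)`
#' so experiments with unequal overlap are comparable (switchable). The
#' relative similarity score is `r_i = d_bar / max(d_i, eps)` where
#' `d_bar` is the panel-mean distance and `eps = 1e-12 * d_bar`: a score
#' of 1 marks an experiment exactly as similar to the signature as the
#' panel average, larger scores mark greater similarity, and ranking by
#' score equals ranking by increasing distance.
#'
#' @param sig A [build_signature()] object (or data.frame with `gene`,
#'   `change`).
#' @param panel Numeric matrix, rows = genes (rownames), columns =
#'   experiment IDs; `NA` cells mark genes absent from an experiment.
#' @param normalize Divide distances by `sqrt(n_shared)` (default TRUE).
#' @return data.frame of class `similarity_result`, sorted by
#'   `relative_score` descending: `experiment`, `n_shared`, `distance`,
#'   `relative_score`, `rank`. Experiments sharing no gene with the
#'   signature are dropped with a warning.
#' @export
rank_panel <- function(sig, panel, normalize = TRUE) {
  stopifnot(is.data.frame(sig), all(c("gene", "change") %in% names(sig)))
  if (is.null(dim(panel)) || ncol(panel) == 0L) stop("empty panel")
  if (is.null(rownames(panel)) || is.null(colnames(panel)))
    stop("panel needs gene rownames and experiment colnames")
  sig_val <- stats::setNames(sig$change, sig$gene)
  res <- lapply(colnames(panel), function(ex) {
    v <- panel[, ex]
    shared <- intersect(sig$gene, rownames(panel)[is.finite(v)])
    if (length(shared) == 0L) return(NULL)
    d <- sqrt(sum((sig_val[shared] - v[shared])^2))
    if (normalize) d <- d / sqrt(length(shared))
    data.frame(experiment = ex, n_shared = length(shared), distance = d,
               stringsAsFactors = FALSE)
  })
  dropped <- colnames(panel)[vapply(res, is.null, TRUE)]
  if (length(dropped))
    warning("experiment(s) share no gene with the signature, dropped: ",
            paste(dropped, collapse = ", "))
  res <- do.call(rbind, res)
  if (is.null(res)) stop("no experiment shares a gene with the signature")
  d_bar <- mean(res$distance)
  if (d_bar == 0) {
    res$relative_score <- rep(1, nrow(res))
  } else {
    eps <- 1e-12 * d_bar
    res$relative_score <- d_bar / pmax(res$distance, eps)
  }
  res <- res[order(-res$relative_score, res$experiment), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("similarity_result", "data.frame")
  res
}

#' Read an experiment panel from a TSV matrix
#'
#' Rows are genes, columns experiment IDs, cells signed change values;
#' blank cells mark genes absent from an experiment.
#'
#' @param path TSV path (first column = gene IDs).
#' @return Numeric matrix with gene rownames.
#' @export
read_panel <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1L, with = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(dt[[1L]])
  m
}

#' Write an experiment panel to TSV
#' @param panel Numeric matrix with gene rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  dt <- data.table::data.table(gene = rownames(panel))
  for (cn in colnames(panel)) dt[[cn]] <- panel[, cn]
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
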