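#' Trinary response-call levels
#'
#' The three admissible response calls, in the display order used
#' throughout the package: `up` (treatment > reference), `nc` (no change)
#' and `down` (treatment < reference).
#'
#' @return Character vector `c("up", "nc", "down")`.
#' @export
call_levels <- function() c("up", "nc", "down")

# token -> canonical call; case-insensitive, accepts signed-integer codes
.call_vocab <- c(
  "up" = "up", "+1" = "up", "1" = "up",
  "nc" = "nc", "0" = "nc", "n" = "nc",
  "down" = "down", "-1" = "down"
)

#' Canonicalise response-call tokens
#'
#' Maps an accepted vocabulary (`up/+1/1`, `nc/0/n`, `down/-1`,
#' case-insensitive) onto the canonical tokens `up`, `nc`, `down`.
#'
#' @param x Character vector of tokens.
#' @return Character vector of canonical tokens; unknown tokens become `NA`.
#' @export
canonical_calls <- function(x) {
  out <- .call_vocab[tolower(trimws(as.character(x)))]
  names(out) <- NULL
  unname(out)
}

#' Construct a validated call table
#'
#' A call table is the universal substrate of the pipeline: a gene x
#' contrast grid in which every cell holds exactly one trinary response
#' call. Gene identifiers must be unique and every listed contrast must
#' have a call (possibly `nc`) for every gene; missingness is modelled by
#' dropping the gene, never by an in-grid missing code, so contingency
#' marginals stay exact.
#'
#' @param calls Character matrix of calls with gene IDs as rownames and
#'   contrast names as colnames. Tokens are canonicalised via
#'   [canonical_calls()].
#' @param provenance Optional free-text metadata string.
#' @return An object of class `call_table`.
#' @export
call_table <- function(calls, provenance = NULL) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("`calls` must have gene rownames and contrast colnames")
  genes <- rownames(calls)
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene identifier(s): ", paste(unique(dup), collapse = ", "))
  if (anyDuplicated(colnames(calls)))
    stop("duplicate contrast name(s): ",
         paste(unique(colnames(calls)[duplicated(colnames(calls))]), collapse = ", "))
  canon <- canonical_calls(calls)
  if (anyNA(canon)) {
    bad <- which(is.na(canon))[1L]
    rc <- arrayInd(bad, dim(calls))
    stop(sprintf("unknown call token '%s' at gene '%s', contrast '%s'",
                 calls[bad], genes[rc[1L]], colnames(calls)[rc[2L]]))
  }
  out <- matrix(canon, nrow = nrow(calls), dimnames = dimnames(calls))
  structure(list(calls = out, provenance = provenance), class = "call_table")
}

#' @export
print.call_table <- function(x, ...) {
  cat(sprintf("call_table: %d genes x %d contrasts (%s)\n",
              nrow(x$calls), ncol(x$calls),
              paste(colnames(x$calls), collapse = ", ")))
  if (!is.null(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
dim.call_table <- function(x) dim(x$calls)

#' Gene identifiers of a call table
#' @param x A `call_table`.
#' @return Character vector of gene IDs.
#' @export
table_genes <- function(x) rownames(x$calls)

#' Contrast names of a call table
#' @param x A `call_table`.
#' @return Character vector of contrast names.
#' @export
table_contrasts <- function(x) colnames(x$calls)

.require_contrasts <- function(table, contrasts) {
  missing <- setdiff(contrasts, table_contrasts(table))
  if (length(missing))
    stop("contrast(s) absent from call table: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Read a call table from TSV
#'
#' Expects a header row `gene<TAB><contrast1><TAB>...` and one row per
#' gene; cells in the accepted trinary vocabulary (see
#' [canonical_calls()]). UTF-8, no quoting.
#'
#' @param path Path to a TSV file.
#' @return A validated [call_table()].
#' @export
read_call_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  if (ncol(dt) < 2L) stop("call-table file needs a gene column and >= 1 contrast")
  genes <- dt[[1L]]
  m <- as.matrix(dt[, -1L, with = FALSE])
  rownames(m) <- genes
  call_table(m, provenance = paste0("read from ", path))
}

#' Write a call table to TSV
#'
#' Inverse of [read_call_table()]; canonical tokens `up/nc/down` are
#' written, so write-then-read round-trips losslessly up to token
#' canonicalisation.
#'
#' @param x A `call_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_call_table <- function(x, path) {
  stopifnot(inherits(x, "call_table"))
  dt <- data.table::data.table(gene = table_genes(x))
  for (cn in table_contrasts(x)) dt[[cn]] <- x$calls[, cn]
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Derive trinary calls from continuous expression changes
#'
#' Documented default rule for turning signed expression changes plus a
#' significance mask into trinary calls: `up` iff significant and change
#' >= `up_threshold`; `down` iff significant and change <=
#' `down_threshold`; otherwise `nc`. Genes with any missing
#' (non-finite, non-significant) change value are dropped and reported
#' via a message and the `dropped` attribute.
#'
#' @param changes Numeric gene x contrast matrix of signed changes
#'   (e.g. log2 fold changes), with gene rownames and contrast colnames.
#' @param significant Logical matrix of the same shape.
#' @param up_threshold Positive real.
#' @param down_threshold Negative real.
#' @return A [call_table()] with attribute `dropped` listing removed genes.
#' @export
derive_calls <- function(changes, significant, up_threshold = 1,
                         down_threshold = -1) {
  stopifnot(is.matrix(changes), identical(dim(changes), dim(significant)))
  if (!(down_threshold < 0 && up_threshold > 0))
    stop("thresholds must satisfy down_threshold < 0 < up_threshold")
  if (any(!is.finite(changes) & significant, na.rm = TRUE))
    stop("non-finite change value flagged significant")
  sig <- significant & !is.na(significant)
  calls <- matrix("nc", nrow(changes), ncol(changes), dimnames = dimnames(changes))
  calls[sig & is.finite(changes) & changes >= up_threshold] <- "up"
  calls[sig & is.finite(changes) & changes <= down_threshold] <- "down"
  incomplete <- apply(changes, 1L, function(r) any(!is.finite(r)))
  dropped <- rownames(changes)[incomplete]
  if (length(dropped))
    message(length(dropped), " gene(s) dropped for missing change values")
  out <- call_table(calls[!incomplete, , drop = FALSE],
                    provenance = sprintf("derived (up >= %g, down <= %g)",
                                         up_threshold, down_threshold))
  attr(out, "dropped") <- dropped
  out
}
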