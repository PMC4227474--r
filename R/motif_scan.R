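#' Construct a promoter set
#'
#' @param sequences Named character vector of uppercase DNA sequences
#'   over `{A,C,G,T,N}`, names = unique gene IDs. Sequences shorter than
#'   the shortest scannable motif (4 bp) are kept but flagged unusable.
#' @return Object of class `promoter_set` (the named character vector,
#'   with attribute `usable`).
#' @export
promoter_set <- function(sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("promoter sequences must be named by gene ID")
  if (anyDuplicated(names(sequences)))
    stop("duplicate promoter gene ID(s): ",
         paste(unique(names(sequences)[duplicated(names(sequences))]),
               collapse = ", "))
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("non-ACGTN character in promoter(s): ",
         paste(utils::head(names(sequences)[bad], 5L), collapse = ", "))
  structure(sequences, usable = nchar(sequences) >= 4L, class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set: %d sequences (%d usable), lengths %d-%d\n",
              length(x), sum(attr(x, "usable")),
              min(nchar(x)), max(nchar(x))))
  invisible(x)
}

#' Read promoters from FASTA
#' @param path FASTA file path.
#' @return A [promoter_set()].
#' @export
read_promoters <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  promoter_set(stats::setNames(as.character(ss),
                               sub("\\s.*$", "", names(ss))))
}

#' Write promoters to FASTA
#' @param x A `promoter_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(x, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(unclass(x)[seq_along(x)],
                                             names(x))), path)
  invisible(path)
}

# vectorised reverse complement of plain character k-mers
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical form of a motif under reverse complementation
#'
#' A motif and its reverse complement are the same double-stranded
#' object; the canonical representative is the lexicographically smaller
#' of the two (palindromes are their own canonical form).
#'
#' @param x Character vector of DNA motifs.
#' @return Character vector of canonical motifs.
#' @export
canonical_motif <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

#' Extract promoter windows from gene coordinates
#'
#' For each gene, the window of up to `max_len` bases immediately
#' upstream of the transcription start site on the gene's strand
#' (reverse-complemented for `-` strand genes), truncated where it would
#' overlap any other gene's annotated span. The window ends at the TSS
#' exclusive, so the 5'UTR is never included. Coordinates are 1-based
#' inclusive; a gene's span is taken as TSS..gene_end on its strand.
#'
#' @param coords data.frame with columns `gene`, `chrom`, `strand`
#'   (`+`/`-`), `tss`, `utr5_end`, `gene_end` (1-based inclusive).
#' @param genome Named character vector (or `DNAStringSet`) of
#'   chromosome sequences.
#' @param max_len Maximum promoter length (default 1000, the
#'   conventional -1000 bp window).
#' @return A [promoter_set()]; genes whose window is fully truncated get
#'   an empty, unusable record.
#' @export
extract_promoters <- function(coords, genome, max_len = 1000) {
  req <- c("gene", "chrom", "strand", "tss", "utr5_end", "gene_end")
  if (!all(req %in% names(coords)))
    stop("coords needs columns: ", paste(req, collapse = ", "))
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome),
                              sub("\\s.*$", "", names(genome)))
  }
  if (!all(coords$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  unknown <- setdiff(coords$chrom, names(genome))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  span_lo <- pmin(coords$tss, coords$gene_end)
  span_hi <- pmax(coords$tss, coords$gene_end)
  out <- character(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    chr <- coords$chrom[i]
    chrlen <- nchar(genome[[chr]])
    tss <- coords$tss[i]
    if (tss < 1L || tss > chrlen)
      stop(sprintf("TSS of gene '%s' outside chromosome '%s'",
                   coords$gene[i], chr))
    others <- which(coords$chrom == chr & seq_len(nrow(coords)) != i)
    if (coords$strand[i] == "+") {
      s <- max(1L, tss - max_len); e <- tss - 1L
      for (j in others) {
        if (span_lo[j] <= e && span_hi[j] >= s)
          s <- max(s, span_hi[j] + 1L)
      }
      out[i] <- if (s <= e) substr(genome[[chr]], s, e) else ""
    } else {
      s <- tss + 1L; e <- min(chrlen, tss + max_len)
      for (j in others) {
        if (span_lo[j] <= e && span_hi[j] >= s)
          e <- min(e, span_lo[j] - 1L)
      }
      out[i] <- if (s <= e) revcomp(substr(genome[[chr]], s, e)) else ""
    }
  }
  names(out) <- coords$gene
  x <- structure(toupper(out), usable = nchar(out) >= 4L,
                 class = "promoter_set")
  if (anyDuplicated(names(out))) stop("duplicate gene IDs in coords")
  x
}

# data.table of unique (promoter index, k-mer) pairs over forward
# strands; k-mers containing N are never counted
.presence_pairs <- function(seqs, kmin, kmax) {
  pid <- integer(0); kmer <- character(0)
  res <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    n <- nchar(s)
    ks <- kmin:kmax
    kms <- unlist(lapply(ks[ks <= n], function(k)
      unique(substring(s, 1:(n - k + 1L), k:n))), use.names = FALSE)
    if (length(kms)) {
      kms <- kms[!grepl("N", kms, fixed = TRUE)]
      res[[i]] <- data.table::data.table(pid = i, kmer = kms)
    }
  }
  data.table::rbindlist(res)
}

#' Exhaustive short-motif over-representation scan
#'
#' Tests every k-mer (`kmin <= k <= kmax`) present in at least one
#' foreground promoter for over-representation against a background
#' promoter set. Counting is presence/absence per promoter on either
#' strand: the 2x2 table contrasts promoters containing >= 1 occurrence
#' of the motif (or its reverse complement) with those that do not,
#' foreground vs background. Significance is a 1-dof chi-squared test
#' without continuity correction; only over-represented motifs
#' (foreground presence rate > background rate) with `p < alpha` are
#' retained. A motif and its reverse complement are merged into one
#' canonical hit ([canonical_motif()]); positions containing `N` never
#' match.
#'
#' @param fg,bg Non-empty [promoter_set()]s (IDs need not be disjoint).
#' @param kmin,kmax Motif length range, default 4-10.
#' @param alpha Significance threshold, default `1e-5`.
#' @return data.frame of class `motif_hits` sorted by p-value:
#'   `motif`, `k`, `fg_present`, `fg_absent`, `bg_present`, `bg_absent`,
#'   `chi2`, `p_value`, `strand_note` (filled by [match_catalog()]);
#'   attribute `n_tested` records the size of the tested motif family.
#' @export
scan_motifs <- function(fg, bg, kmin = 4, kmax = 10, alpha = 1e-5) {
  stopifnot(inherits(fg, "promoter_set"), inherits(bg, "promoter_set"))
  if (kmin > kmax) stop("kmin > kmax")
  if (kmin < 1) stop("kmin must be >= 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (length(fg) == 0L || length(bg) == 0L) stop("empty promoter set")
  n_fg <- length(fg); n_bg <- length(bg)
  pairs_fg <- .presence_pairs(unclass(fg)[seq_len(n_fg)], kmin, kmax)
  pairs_bg <- .presence_pairs(unclass(bg)[seq_len(n_bg)], kmin, kmax)
  pairs <- data.table::rbindlist(list(
    data.table::data.table(grp = "fg", pairs_fg),
    data.table::data.table(grp = "bg", pairs_bg)))
  if (nrow(pairs) == 0L) stop("no scannable k-mers (promoters too short?)")
  uk <- unique(pairs$kmer)
  canon_map <- stats::setNames(canonical_motif(uk), uk)
  pairs[, "canon" := canon_map[pairs$kmer]]
  # a promoter carrying both a motif and its reverse complement counts once
  pres <- unique(pairs[, c("grp", "pid", "canon")])
  counts <- pres[, list(n = .N), by = c("grp", "canon")]
  wide <- data.table::dcast(counts, canon ~ grp, value.var = "n", fill = 0L)
  if (!"bg" %in% names(wide)) wide[, "bg" := 0L]
  if (!"fg" %in% names(wide)) wide[, "fg" := 0L]
  wide <- wide[wide$fg >= 1L]  # tested family: present in >= 1 fg promoter
  n_tested <- nrow(wide)
  a <- wide$fg; b <- n_fg - a; cc <- wide$bg; dd <- n_bg - cc
  N <- n_fg + n_bg
  denom <- as.numeric(a + b) * (cc + dd) * (a + cc) * (b + dd)
  chi2 <- ifelse(denom > 0,
                 N * (as.numeric(a) * dd - as.numeric(b) * cc)^2 / denom, 0)
  p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  over <- a / n_fg > cc / n_bg
  keep <- which(p < alpha & over)
  hits <- data.frame(
    motif = wide$canon[keep], k = nchar(wide$canon[keep]),
    fg_present = a[keep], fg_absent = b[keep],
    bg_present = cc[keep], bg_absent = dd[keep],
    chi2 = chi2[keep], p_value = p[keep],
    strand_note = rep(NA_character_, length(keep)), stringsAsFactors = FALSE)
  hits <- hits[order(hits$p_value, hits$motif), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "n_tested") <- n_tested
  class(hits) <- c("motif_hits", "data.frame")
  hits
}

# ---- IUPAC matching ---------------------------------------------------

.iupac_classes <- function(pattern) {
  chars <- strsplit(pattern, "")[[1L]]
  map <- Biostrings::IUPAC_CODE_MAP
  bad <- setdiff(chars, names(map))
  if (length(bad))
    stop("invalid IUPAC character(s): ", paste(unique(bad), collapse = ", "))
  unname(map[chars])
}

# does `motif` (plain ACGT) contain a window matching `pattern`, or fit
# inside `pattern` at some offset?
.iupac_dir_match <- function(motif, pattern) {
  classes <- .iupac_classes(pattern)
  np <- length(classes); nm <- nchar(motif)
  mchars <- strsplit(motif, "")[[1L]]
  if (nm >= np) {
    rx <- paste0(vapply(classes, function(cl) paste0("[", cl, "]"), ""),
                 collapse = "")
    return(grepl(rx, motif))
  }
  for (off in 0:(np - nm)) {
    ok <- TRUE
    for (j in seq_len(nm)) {
      if (!grepl(mchars[j], classes[off + j], fixed = TRUE)) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

#' Match a motif against an IUPAC cis-element pattern
#'
#' A motif matches an element if the motif (or its reverse complement)
#' contains a string matching the IUPAC pattern, or is contained in one.
#'
#' @param motif Plain ACGT motif string.
#' @param pattern IUPAC degenerate pattern (codes A,C,G,T,M,R,W,S,Y,K,
#'   V,H,D,B,N).
#' @return `"forward"`, `"reverse"`, `"both"` or `NA_character_` (no
#'   match).
#' @export
iupac_match <- function(motif, pattern) {
  fwd <- .iupac_dir_match(motif, pattern)
  rev <- .iupac_dir_match(revcomp(motif), pattern)
  if (fwd && rev) "both" else if (fwd) "forward" else if (rev) "reverse"
  else NA_character_
}

#' Annotate motif hits with known cis-elements
#'
#' @param hits A `motif_hits` data.frame from [scan_motifs()].
#' @param catalog data.frame with columns `name` and `pattern` (IUPAC).
#' @return `hits` with `catalog_match` (collapsed `name(strand)` list,
#'   `""` if none) and `strand_note` (strand of the first match);
#'   attribute `catalog_matches` holds the long (motif, element,
#'   pattern, strand) table.
#' @export
match_catalog <- function(hits, catalog) {
  stopifnot(is.data.frame(catalog), all(c("name", "pattern") %in% names(catalog)))
  long <- list()
  match_str <- character(nrow(hits))
  strand_note <- rep(NA_character_, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    found <- character(0)
    for (j in seq_len(nrow(catalog))) {
      s <- iupac_match(hits$motif[i], catalog$pattern[j])
      if (!is.na(s)) {
        found <- c(found, sprintf("%s(%s)", catalog$name[j], s))
        if (is.na(strand_note[i])) strand_note[i] <- s
        long[[length(long) + 1L]] <- data.frame(
          motif = hits$motif[i], element = catalog$name[j],
          pattern = catalog$pattern[j], strand = s, stringsAsFactors = FALSE)
      }
    }
    match_str[i] <- paste(found, collapse = ";")
  }
  hits$catalog_match <- match_str
  hits$strand_note <- strand_note
  attr(hits, "catalog_matches") <- if (length(long)) do.call(rbind, long) else
    data.frame(motif = character(0), element = character(0),
               pattern = character(0), strand = character(0))
  hits
}

#' Prune nested motif hits
#'
#' Within each containment chain (a shorter significant motif inside a
#' longer one, in either orientation), keeps only the hit with the
#' smallest p-value.
#'
#' @param hits A `motif_hits` data.frame.
#' @return The pruned data.frame.
#' @export
prune_nested <- function(hits) {
  if (nrow(hits) < 2L) return(hits)
  m <- hits$motif; mrc <- revcomp(m); p <- hits$p_value
  contains <- function(long, short, short_rc)
    grepl(short, long, fixed = TRUE) || grepl(short_rc, long, fixed = TRUE)
  drop <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    for (j in seq_len(nrow(hits))) {
      if (i == j) next
      nested <- if (nchar(m[i]) <= nchar(m[j]))
        contains(m[j], m[i], mrc[i]) else contains(m[i], m[j], mrc[j])
      if (nested && (p[j] < p[i] || (p[j] == p[i] && j < i))) {
        drop[i] <- TRUE; break
      }
    }
  }
  out <- hits[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write motif hits to TSV
#' @param hits A `motif_hits` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_hits <- function(hits, path) {
  data.table::fwrite(as.data.frame(hits), path, sep = "\t", quote = FALSE)
  invisible(path)
}
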