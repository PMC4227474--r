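#' Construct a gene -> category annotation map
#'
#' Many-to-many annotation (GO-slim style): a gene may carry several
#' categories and counts once per category. Genes in the background
#' universe without any annotation dilute frequencies by default (see
#' `annotated_only` in [enrichment()]).
#'
#' @param gene,category Equal-length character vectors of annotation
#'   pairs (repeated genes for multi-annotation).
#' @param universe Background gene universe; defaults to the annotated
#'   genes. Every annotated gene must be in the universe.
#' @return Object of class `annotation_map` with components `pairs`
#'   (data.table gene/category) and `universe`.
#' @export
annotation_map <- function(gene, category, universe = unique(gene)) {
  stopifnot(length(gene) == length(category))
  if (any(!nzchar(category))) stop("empty category identifier")
  extra <- setdiff(gene, universe)
  if (length(extra))
    stop("annotated gene(s) outside the universe: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  pairs <- unique(data.table::data.table(gene = as.character(gene),
                                         category = as.character(category)))
  structure(list(pairs = pairs, universe = unique(as.character(universe))),
            class = "annotation_map")
}

#' Read an annotation map from two-column TSV
#'
#' @param path TSV with columns `gene`, `category` (header required);
#'   repeated rows express multi-annotation.
#' @param universe Optional background universe (defaults to annotated
#'   genes).
#' @return An [annotation_map()].
#' @export
read_annotation_map <- function(path, universe = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (ncol(dt) < 2L) stop("annotation file needs two columns (gene, category)")
  if (is.null(universe)) universe <- unique(dt[[1L]])
  annotation_map(dt[[1L]], dt[[2L]], universe)
}

# per-category annotation frequency of `genes` (with multiplicity)
.category_freq <- function(genes, ann, categories) {
  counts <- stats::setNames(numeric(length(categories)), categories)
  hit <- ann$pairs[ann$pairs$gene %in% unique(genes)]
  if (nrow(hit)) {
    mult <- table(genes)[hit$gene]  # resampling multiplicity
    agg <- tapply(as.numeric(mult), hit$category, sum)
    counts[names(agg)] <- agg
  }
  counts / length(genes)
}

#' Background-normalised category enrichment of a gene set
#'
#' For every category, the fraction of set genes annotated to it divided
#' by the fraction of universe genes annotated to it — the
#' frequency-normalised enrichment ratio. Point estimates only; see
#' [bootstrap_enrichment()] for bootstrap mean and SD.
#'
#' @param set Character vector of gene IDs, non-empty subset of the
#'   universe.
#' @param ann An [annotation_map()].
#' @param annotated_only If `TRUE`, restrict both the set and the
#'   universe to genes carrying at least one annotation.
#' @return data.frame of class `enrichment_profile`: `category`,
#'   `set_frequency`, `background_frequency`, `ratio` (`NA` where the
#'   background frequency is zero).
#' @export
enrichment <- function(set, ann, annotated_only = FALSE) {
  stopifnot(inherits(ann, "annotation_map"))
  if (length(set) == 0L) stop("empty gene set")
  outside <- setdiff(set, ann$universe)
  if (length(outside))
    stop("set members outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  universe <- ann$universe
  if (annotated_only) {
    annotated <- unique(ann$pairs$gene)
    universe <- intersect(universe, annotated)
    set <- intersect(set, annotated)
    if (length(set) == 0L) stop("no annotated genes in set")
  }
  categories <- sort(unique(ann$pairs$category))
  sf <- .category_freq(set, ann, categories)
  bf <- .category_freq(universe, ann, categories)
  out <- data.frame(category = categories, set_frequency = unname(sf),
                    background_frequency = unname(bf),
                    ratio = unname(ifelse(bf > 0, sf / bf, NA_real_)),
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_profile", "data.frame")
  out
}

#' Bootstrap mean and SD of category-enrichment ratios
#'
#' Each replicate resamples `|set|` genes from the input set with
#' replacement (the resampling unit is the gene) and recomputes the
#' normalised ratios; `boot_mean` and `boot_sd` are the per-category
#' replicate mean and sample SD. Deterministic under a fixed seed.
#'
#' @inheritParams enrichment
#' @param n_boot Number of bootstrap replicates (>= 2); 100 by default.
#' @param seed Integer RNG seed.
#' @return The [enrichment()] data.frame with added columns `boot_mean`,
#'   `boot_sd`, `n_boot`.
#' @export
bootstrap_enrichment <- function(set, ann, n_boot = 100, seed = 1,
                                 annotated_only = FALSE) {
  stopifnot(n_boot >= 2)
  point <- enrichment(set, ann, annotated_only = annotated_only)
  if (annotated_only) set <- intersect(set, unique(ann$pairs$gene))
  bf <- point$background_frequency
  categories <- point$category
  reps <- matrix(NA_real_, nrow = n_boot, ncol = length(categories))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    resample <- sample(set, length(set), replace = TRUE)
    sf <- .category_freq(resample, ann, categories)
    reps[b, ] <- ifelse(bf > 0, sf / bf, NA_real_)
  }
  point$boot_mean <- colMeans(reps)
  point$boot_sd <- apply(reps, 2L, stats::sd)
  point$n_boot <- n_boot
  point
}

#' Write an enrichment profile to TSV
#' @param x An `enrichment_profile` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", quote = FALSE)
  invisible(path)
}
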