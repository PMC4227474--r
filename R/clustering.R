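#' Classify SA-responsive genes into mechanistic clusters A, B, C, D
#'
#' Implements the step-wise call-pattern classification of
#' hormone-responsive genes over four contrasts: the hormone response
#' (`sa`), a PI-PLC inhibitor response (`inhibitor`, edelfosine or
#' U73122), the basal wortmannin contrast (`w30_basal`, W30 vs W1) and
#' the wortmannin-under-SA contrast (`w30_sa`, SAW30 vs SAW1).
#'
#' Over genes with `sa = up`, applied in order:
#' \enumerate{
#'   \item discard genes unaffected by the inhibitor and by wortmannin
#'     (all three of inhibitor, W30 basal, W30-under-SA are `nc`);
#'   \item cluster A (induction dependent on phosphoinositides):
#'     `w30_sa = down`, `w30_basal != up`, `inhibitor != down`;
#'   \item cluster B (induction via loss of PI-PLC-product repression):
#'     `inhibitor = up`, `w30_basal = up`, `w30_sa != down`.
#' }
#' Over genes with `sa = down`:
#' \enumerate{
#'   \item discard genes with no alteration on inhibitor / W30 / SAW30;
#'   \item cluster D (repression dependent on phosphoinositides):
#'     `w30_sa = up`, `w30_basal != down`, and by default
#'     `inhibitor != up` (see `d_excludes_inhibitor_up`);
#'   \item cluster C, on genes not labelled D (repression via loss of
#'     PI-PLC-product induction): `inhibitor = down`, `w30_basal = down`,
#'     optionally `w30_sa != up` (off by default).
#' }
#' A and B are mutually exclusive (A needs `w30_sa = down`, B forbids
#' it); C and D are exclusive because C is evaluated after removing D.
#'
#' Variant labels mark near-misses, never supersets: `B^X` satisfies B
#' except the basal W30 induction (`inhibitor = up` only), `B^W30`
#' satisfies B except the inhibitor induction (`w30_basal = up` only);
#' `C^X` and `C^W30` analogously for the repression conditions,
#' evaluated on genes not labelled C or D.
#'
#' @param table A [call_table()] with calls for all four contrasts.
#' @param inhibitor Name of the inhibitor contrast (e.g. `"EDE"` or
#'   `"U73"`).
#' @param sa,w30_basal,w30_sa Contrast names; defaults `"SA"`, `"W30B"`,
#'   `"W30SA"`.
#' @param d_excludes_inhibitor_up The narrative states no
#'   inhibitor-direction exclusion for cluster D; by symmetry with
#'   cluster A's exclusion the default additionally requires
#'   `inhibitor != up` for D. Set `FALSE` for the literal rule set.
#' @param c_excludes_w30sa_up Optional `w30_sa != up` guard on cluster C
#'   (and its variants); off by default.
#' @return Object of class `cluster_assignment`: `labels` (named gene ->
#'   one of `A`, `B`, `C`, `D`, `none`), `variant_labels` (named list
#'   gene -> character vector among `B^X`, `B^W30`, `C^X`, `C^W30`),
#'   `audit` (named gene -> decisive rule outcome), `inhibitor`,
#'   `universe`.
#' @export
assign_clusters <- function(table, inhibitor, sa = "SA", w30_basal = "W30B",
                            w30_sa = "W30SA",
                            d_excludes_inhibitor_up = TRUE,
                            c_excludes_w30sa_up = FALSE) {
  stopifnot(inherits(table, "call_table"))
  needed <- c(sa, inhibitor, w30_basal, w30_sa)
  missing <- setdiff(needed, table_contrasts(table))
  if (length(missing))
    stop("required contrast(s) absent: ", paste(missing, collapse = ", "))
  genes <- table_genes(table)
  S <- table$calls[, sa]
  X <- table$calls[, inhibitor]
  WB <- table$calls[, w30_basal]
  WS <- table$calls[, w30_sa]

  labels <- stats::setNames(rep("none", length(genes)), genes)
  audit <- stats::setNames(rep("not SA-responsive", length(genes)), genes)
  variants <- rep(list(character(0)), length(genes))
  names(variants) <- genes

  unaffected <- X == "nc" & WB == "nc" & WS == "nc"

  ## SA-induced branch
  up <- S == "up"
  audit[up & unaffected] <- "discarded: unaffected by inhibitor or W30"
  live <- up & !unaffected
  is_a <- live & WS == "down" & WB != "up" & X != "down"
  is_b <- live & X == "up" & WB == "up" & WS != "down"
  labels[is_a] <- "A"
  labels[is_b] <- "B"
  audit[is_a] <- "A: SAW30-repressed, basal/inhibitor compatible"
  audit[is_b] <- "B: induced by inhibitor and W30"
  bx <- live & !is_a & !is_b & X == "up" & WB != "up" & WS != "down"
  bw <- live & !is_a & !is_b & WB == "up" & X != "up" & WS != "down"
  for (i in which(bx)) variants[[i]] <- c(variants[[i]], "B^X")
  for (i in which(bw)) variants[[i]] <- c(variants[[i]], "B^W30")
  audit[live & labels == "none"] <- "discarded: fails A and B predicates"

  ## SA-repressed branch
  dn <- S == "down"
  audit[dn & unaffected] <- "discarded: unaffected by inhibitor or W30"
  live <- dn & !unaffected
  is_d <- live & WS == "up" & WB != "down"
  if (d_excludes_inhibitor_up) is_d <- is_d & X != "up"
  c_ok <- if (c_excludes_w30sa_up) WS != "up" else rep(TRUE, length(genes))
  is_c <- live & !is_d & X == "down" & WB == "down" & c_ok
  labels[is_d] <- "D"
  labels[is_c] <- "C"
  audit[is_d] <- "D: SAW30-derepressed, basal compatible"
  audit[is_c] <- "C: repressed by inhibitor and W30"
  cx <- live & !is_d & !is_c & X == "down" & WB != "down" & c_ok
  cw <- live & !is_d & !is_c & WB == "down" & X != "down" & c_ok
  for (i in which(cx)) variants[[i]] <- c(variants[[i]], "C^X")
  for (i in which(cw)) variants[[i]] <- c(variants[[i]], "C^W30")
  audit[live & labels == "none"] <- "discarded: fails C and D predicates"

  structure(list(labels = labels, variant_labels = variants, audit = audit,
                 inhibitor = inhibitor, universe = genes,
                 rules = list(d_excludes_inhibitor_up = d_excludes_inhibitor_up,
                              c_excludes_w30sa_up = c_excludes_w30sa_up)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment (inhibitor = %s):\n", x$inhibitor))
  print(table(factor(x$labels, levels = c("A", "B", "C", "D", "none"))))
  invisible(x)
}

#' Genes carrying a given cluster label
#' @param x A `cluster_assignment`.
#' @param cluster One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return Character vector of gene IDs.
#' @export
cluster_members <- function(x, cluster) {
  stopifnot(inherits(x, "cluster_assignment"))
  names(x$labels)[x$labels == cluster]
}

#' Reconcile two single-inhibitor cluster assignments
#'
#' A gene belongs to a *stringent* cluster if it carries the label under
#' both inhibitor analyses (per-cluster intersection), and to a *loose*
#' cluster if it carries it under at least one (union), so
#' stringent \eqn{\subseteq} each per-inhibitor set \eqn{\subseteq} loose.
#'
#' @param a1,a2 `cluster_assignment` objects over the same gene universe.
#' @return Object of class `reconciled_clusters`: `stringent` and
#'   `loose` (named lists cluster -> sorted gene vector) and
#'   `per_inhibitor` (the two inputs).
#' @export
reconcile <- function(a1, a2) {
  stopifnot(inherits(a1, "cluster_assignment"),
            inherits(a2, "cluster_assignment"))
  sym <- c(setdiff(a1$universe, a2$universe), setdiff(a2$universe, a1$universe))
  if (length(sym))
    stop("assignments cover different universes; symmetric difference: ",
         paste(utils::head(sym, 5L), collapse = ", "),
         if (length(sym) > 5L) sprintf(" (+%d more)", length(sym) - 5L))
  cl <- c("A", "B", "C", "D")
  stringent <- lapply(cl, function(k)
    sort(intersect(cluster_members(a1, k), cluster_members(a2, k))))
  loose <- lapply(cl, function(k)
    sort(union(cluster_members(a1, k), cluster_members(a2, k))))
  names(stringent) <- names(loose) <- cl
  structure(list(stringent = stringent, loose = loose,
                 per_inhibitor = list(a1, a2)),
            class = "reconciled_clusters")
}

#' @export
print.reconciled_clusters <- function(x, ...) {
  s <- vapply(x$stringent, length, 0L)
  l <- vapply(x$loose, length, 0L)
  cat("reconciled clusters (stringent / loose):\n")
  for (k in names(s)) cat(sprintf("  %s: %d / %d\n", k, s[k], l[k]))
  invisible(x)
}

#' Cluster shares of the SA-responsive gene pools
#'
#' Expresses cluster sizes as percentages of the SA-induced pool (A, B)
#' and the SA-repressed pool (C, D), rounded to the nearest percent.
#'
#' @param sizes Named numeric vector with entries `A`, `B`, `C`, `D`.
#' @param n_induced,n_repressed Pool sizes.
#' @return Named numeric vector of integer percentages.
#' @export
cluster_shares <- function(sizes, n_induced, n_repressed) {
  pool <- c(A = n_induced, B = n_induced, C = n_repressed, D = n_repressed)
  round(100 * sizes[names(pool)] / pool)
}

#' Modifier-response profile of reconciled clusters
#'
#' For each cluster and each trinary level of a modifier contrast
#' (e.g. the PLD-dependency or DGK-inhibitor contrast), counts cluster
#' members with that call, the count expected from the universe level
#' fraction, and the fold over-representation (via
#' [modifier_overrepresentation()]).
#'
#' @param rc A `reconciled_clusters` object.
#' @param table The [call_table()] carrying the modifier contrast.
#' @param modifier Contrast name.
#' @param which `"stringent"` (default) or `"loose"`.
#' @return data.frame with columns `cluster`, `level`, `n_cluster`,
#'   `observed`, `expected`, `fold`; clusters of size 0 are omitted.
#' @export
cluster_modifier_profile <- function(rc, table, modifier,
                                     which = c("stringent", "loose")) {
  stopifnot(inherits(rc, "reconciled_clusters"))
  which <- match.arg(which)
  sets <- rc[[which]]
  out <- list()
  for (k in names(sets)) {
    members <- intersect(sets[[k]], table_genes(table))
    if (length(members) == 0L) next
    for (lev in call_levels()) {
      m <- modifier_overrepresentation(members, table, modifier, lev)
      out[[length(out) + 1L]] <- data.frame(
        cluster = k, level = lev, n_cluster = length(members),
        observed = m$observed, expected = m$expected, fold = m$fold,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(cluster = character(0), level = character(0),
                      n_cluster = integer(0), observed = integer(0),
                      expected = numeric(0), fold = numeric(0)))
  do.call(rbind, out)
}

#' Write cluster memberships to TSV with a JSON size summary
#'
#' @param rc A `reconciled_clusters` object.
#' @param tsv_path Output TSV (gene, cluster, mode, inhibitors, variants).
#' @param json_path Output JSON of stringent/loose sizes.
#' @return `tsv_path`, invisibly.
#' @export
write_clusters <- function(rc, tsv_path,
                           json_path = sub("\\.tsv$", ".json", tsv_path)) {
  stopifnot(inherits(rc, "reconciled_clusters"))
  a1 <- rc$per_inhibitor[[1L]]; a2 <- rc$per_inhibitor[[2L]]
  rows <- list()
  for (k in names(rc$loose)) {
    for (g in rc$loose[[k]]) {
      inh <- c(if (a1$labels[g] == k) a1$inhibitor,
               if (a2$labels[g] == k) a2$inhibitor)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, cluster = k,
        mode = if (g %in% rc$stringent[[k]]) "stringent" else "loose",
        inhibitors = paste(inh, collapse = ","),
        variants = paste(unique(c(a1$variant_labels[[g]],
                                  a2$variant_labels[[g]])), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  dt <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), cluster = character(0),
               mode = character(0), inhibitors = character(0),
               variants = character(0))
  data.table::fwrite(dt, tsv_path, sep = "\t", quote = FALSE)
  jsonlite::write_json(list(
    stringent = lapply(rc$stringent, length),
    loose = lapply(rc$loose, length)
  ), json_path, auto_unbox = TRUE)
  invisible(tsv_path)
}
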