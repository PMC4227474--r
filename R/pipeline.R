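## End-to-end orchestration: one JSON config drives every stage, outputs
## land in a run directory together with a reproducibility manifest.

config_error <- function(...) {
  stop(structure(class = c("respmode_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1L))))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "respmode_config_error"))
      config_error(sprintf("[stage %s] %s", name, conditionMessage(e)))
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Read a pipeline run configuration (JSON)
#'
#' @param path JSON config path. Recognised top-level keys: `seed`,
#'   `out_dir`, `calls` (TSV path), `contrast_map` (object mapping file
#'   column names onto canonical contrast names), and per-stage objects
#'   `crosstab`, `cluster`, `enrichment`, `motifs`, `similarity`; any
#'   stage may be omitted.
#' @return The config as a named list, with `config_path` recorded.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) config_error("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$config_path <- normalizePath(path)
  cfg
}

#' Run the full pipeline from one configuration
#'
#' Executes the configured stages in order — call-table input,
#' cross-tabulation, cluster assignment/reconciliation, category
#' enrichment, motif scan, similarity ranking — writing each stage's
#' outputs plus a manifest (`manifest.json`: package and R versions,
#' seed, config hash, per-output MD5 checksums) into `out_dir`. All
#' randomness derives from `seed`, so a rerun with an identical config
#' reproduces byte-identical outputs. Any stage failure halts with a
#' stage-tagged error.
#'
#' @param config A config list from [read_run_config()] (or equivalent).
#' @param out_dir Output directory; defaults to `config$out_dir`.
#' @return Invisibly, the manifest list.
#' @export
run_all <- function(config, out_dir = config$out_dir) {
  if (is.null(out_dir)) config_error("no output directory configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outputs <- character(0)
  note <- function(p) outputs <<- c(outputs, p)

  tab <- .stage("calls", {
    if (is.null(config$calls)) config_error("no call-table input configured")
    if (!file.exists(config$calls))
      config_error("call table not found: ", config$calls)
    tab <- read_call_table(config$calls)
    if (!is.null(config$contrast_map)) {
      cm <- unlist(config$contrast_map)  # file column -> canonical name
      absent <- setdiff(names(cm), table_contrasts(tab))
      if (length(absent))
        config_error("contrast_map refers to absent column(s): ",
                     paste(absent, collapse = ", "))
      cn <- table_contrasts(tab)
      cn[match(names(cm), cn)] <- unname(cm)
      colnames(tab$calls) <- cn
    }
    tab
  })

  if (!is.null(config$crosstab)) .stage("crosstab", {
    ct <- config$crosstab
    if (is.null(ct$row_factors) || is.null(ct$col_factor))
      config_error("crosstab needs row_factors and col_factor")
    missing <- setdiff(c(ct$row_factors, ct$col_factor), table_contrasts(tab))
    if (length(missing))
      config_error("crosstab contrast(s) not in call table: ",
                   paste(missing, collapse = ", "))
    res <- cross_tabulate(tab, ct$row_factors, ct$col_factor)
    note(write_contingency(res, file.path(out_dir, "crosstab.tsv")))
    note(file.path(out_dir, "crosstab.json"))
  })

  rc <- NULL
  if (!is.null(config$cluster)) rc <- .stage("cluster", {
    cl <- config$cluster
    inh <- cl$inhibitors
    if (is.null(inh) || length(inh) != 2L)
      config_error("cluster stage needs exactly two inhibitors")
    missing <- setdiff(c("SA", inh, "W30B", "W30SA"), table_contrasts(tab))
    if (length(missing))
      config_error("cluster contrast(s) not in call table: ",
                   paste(missing, collapse = ", "))
    opts <- list(
      d_excludes_inhibitor_up =
        !isFALSE(cl$d_excludes_inhibitor_up),
      c_excludes_w30sa_up = isTRUE(cl$c_excludes_w30sa_up))
    a1 <- do.call(assign_clusters, c(list(tab, inh[1L]), opts))
    a2 <- do.call(assign_clusters, c(list(tab, inh[2L]), opts))
    rc <- reconcile(a1, a2)
    note(write_clusters(rc, file.path(out_dir, "clusters.tsv")))
    note(file.path(out_dir, "clusters.json"))
    if (!is.null(cl$modifier)) {
      prof <- cluster_modifier_profile(rc, tab, cl$modifier)
      p <- file.path(out_dir, "cluster_modifier_profile.tsv")
      data.table::fwrite(prof, p, sep = "\t", quote = FALSE)
      note(p)
    }
    rc
  })

  if (!is.null(config$enrichment)) .stage("enrichment", {
    en <- config$enrichment
    if (is.null(en$annotation))
      config_error("enrichment stage needs an annotation file")
    if (!file.exists(en$annotation))
      config_error("annotation file not found: ", en$annotation)
    ann <- read_annotation_map(en$annotation, universe = table_genes(tab))
    set <- if (!is.null(en$cluster)) {
      if (is.null(rc)) config_error("enrichment over a cluster needs the ",
                                    "cluster stage")
      mode <- if (is.null(en$mode)) "stringent" else en$mode
      rc[[mode]][[en$cluster]]
    } else if (!is.null(en$genes_file)) {
      readLines(en$genes_file)
    } else config_error("enrichment needs `cluster` or `genes_file`")
    if (length(set) == 0L) config_error("enrichment gene set is empty")
    n_boot <- if (is.null(en$n_boot)) 100L else as.integer(en$n_boot)
    prof <- bootstrap_enrichment(set, ann, n_boot = n_boot, seed = seed)
    note(write_enrichment(prof, file.path(out_dir, "enrichment.tsv")))
  })

  if (!is.null(config$motifs)) .stage("motifs", {
    mo <- config$motifs
    for (f in c(mo$fg_fasta, mo$bg_fasta))
      if (!file.exists(f)) config_error("promoter FASTA not found: ", f)
    fg <- read_promoters(mo$fg_fasta)
    bg <- read_promoters(mo$bg_fasta)
    hits <- scan_motifs(fg, bg,
                        kmin = if (is.null(mo$kmin)) 4 else mo$kmin,
                        kmax = if (is.null(mo$kmax)) 10 else mo$kmax,
                        alpha = if (is.null(mo$alpha)) 1e-5 else mo$alpha)
    if (!is.null(mo$catalog)) {
      cat_dt <- data.table::fread(mo$catalog, sep = "\t", header = TRUE,
                                  colClasses = "character")
      hits <- match_catalog(hits, as.data.frame(cat_dt))
    }
    if (isTRUE(mo$prune_nested)) hits <- prune_nested(hits)
    note(write_motif_hits(hits, file.path(out_dir, "motif_hits.tsv")))
  })

  if (!is.null(config$similarity)) .stage("similarity", {
    si <- config$similarity
    if (is.null(si$panel) || !file.exists(si$panel))
      config_error("similarity stage needs an existing panel TSV")
    panel <- read_panel(si$panel)
    changes <- if (!is.null(si$changes)) {
      dt <- data.table::fread(si$changes, sep = "\t", header = TRUE)
      stats::setNames(as.numeric(dt[[2L]]), as.character(dt[[1L]]))
    } else config_error("similarity stage needs a `changes` TSV ",
                        "(gene, change)")
    n_top <- if (is.null(si$n_top)) 200L else as.integer(si$n_top)
    sig <- build_signature(changes, n_top = n_top,
                           direction_only = isTRUE(si$direction_only))
    res <- rank_panel(sig, panel)
    p <- file.path(out_dir, "similarity.tsv")
    data.table::fwrite(res, p, sep = "\t", quote = FALSE)
    note(p)
  })

  manifest <- list(
    package = "respmode",
    version = as.character(utils::packageVersion("respmode")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config_md5 = if (!is.null(config$config_path))
      unname(tools::md5sum(config$config_path)) else NA,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(outputs)), basename(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.cli_opts <- function(rest, ...) {
  parser <- optparse::OptionParser(option_list = list(...))
  optparse::parse_args(parser, args = rest)
}

.opt <- function(name, type = "character", default = NULL)
  optparse::make_option(paste0("--", name), type = type, default = default)

.cli_crosstab <- function(rest) {
  o <- .cli_opts(rest, .opt("calls"), .opt("rows"), .opt("col"), .opt("out"))
  for (k in c("calls", "rows", "col", "out"))
    if (is.null(o[[k]])) config_error("crosstab: --", k, " is required")
  tab <- read_call_table(o$calls)
  res <- cross_tabulate(tab, strsplit(o$rows, ",")[[1L]], o$col)
  dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
  write_contingency(res, file.path(o$out, "crosstab.tsv"))
}

.cli_cluster <- function(rest) {
  o <- .cli_opts(rest, .opt("calls"), .opt("inhibitors"), .opt("out"),
                 .opt("modifier"),
                 .opt("d-excludes-inhibitor-up", "logical", TRUE))
  for (k in c("calls", "inhibitors", "out"))
    if (is.null(o[[k]])) config_error("cluster: --", k, " is required")
  inh <- strsplit(o$inhibitors, ",")[[1L]]
  if (length(inh) != 2L) config_error("cluster: need two inhibitors")
  tab <- read_call_table(o$calls)
  dx <- o$`d-excludes-inhibitor-up`
  rc <- reconcile(
    assign_clusters(tab, inh[1L], d_excludes_inhibitor_up = dx),
    assign_clusters(tab, inh[2L], d_excludes_inhibitor_up = dx))
  dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
  write_clusters(rc, file.path(o$out, "clusters.tsv"))
  if (!is.null(o$modifier)) {
    prof <- cluster_modifier_profile(rc, tab, o$modifier)
    data.table::fwrite(prof, file.path(o$out, "cluster_modifier_profile.tsv"),
                       sep = "\t", quote = FALSE)
  }
}

.cli_enrich <- function(rest) {
  o <- .cli_opts(rest, .opt("genes"), .opt("annotation"), .opt("out"),
                 .opt("n-boot", "integer", 100L), .opt("seed", "integer", 1L))
  for (k in c("genes", "annotation", "out"))
    if (is.null(o[[k]])) config_error("enrich: --", k, " is required")
  ann <- read_annotation_map(o$annotation)
  prof <- bootstrap_enrichment(readLines(o$genes), ann,
                               n_boot = o$`n-boot`, seed = o$seed)
  dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
  write_enrichment(prof, file.path(o$out, "enrichment.tsv"))
}

.cli_scan <- function(rest) {
  o <- .cli_opts(rest, .opt("fg"), .opt("bg"), .opt("out"), .opt("catalog"),
                 .opt("kmin", "integer", 4L), .opt("kmax", "integer", 10L),
                 .opt("alpha", "double", 1e-5),
                 .opt("prune-nested", "logical", FALSE))
  for (k in c("fg", "bg", "out"))
    if (is.null(o[[k]])) config_error("scan: --", k, " is required")
  hits <- scan_motifs(read_promoters(o$fg), read_promoters(o$bg),
                      kmin = o$kmin, kmax = o$kmax, alpha = o$alpha)
  if (!is.null(o$catalog)) {
    cat_dt <- data.table::fread(o$catalog, sep = "\t", header = TRUE,
                                colClasses = "character")
    hits <- match_catalog(hits, as.data.frame(cat_dt))
  }
  if (isTRUE(o$`prune-nested`)) hits <- prune_nested(hits)
  dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
  write_motif_hits(hits, file.path(o$out, "motif_hits.tsv"))
}

.cli_rank <- function(rest) {
  o <- .cli_opts(rest, .opt("panel"), .opt("changes"), .opt("out"),
                 .opt("n-top", "integer", 200L),
                 .opt("direction-only", "logical", FALSE))
  for (k in c("panel", "changes", "out"))
    if (is.null(o[[k]])) config_error("rank: --", k, " is required")
  dt <- data.table::fread(o$changes, sep = "\t", header = TRUE)
  changes <- stats::setNames(as.numeric(dt[[2L]]), as.character(dt[[1L]]))
  sig <- build_signature(changes, n_top = o$`n-top`,
                         direction_only = isTRUE(o$`direction-only`))
  res <- rank_panel(sig, read_panel(o$panel))
  dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(res, file.path(o$out, "similarity.tsv"),
                     sep = "\t", quote = FALSE)
}

.cli_simulate <- function(rest) {
  what <- rest[1L]
  o <- .cli_opts(rest[-1L], .opt("spec"), .opt("out"),
                 .opt("seed", "integer", NULL))
  if (is.na(what) ||
      !what %in% c("calls", "clusters", "promoters", "annotations", "panel"))
    config_error("simulate: first argument must be one of ",
                 "calls|clusters|promoters|annotations|panel")
  if (is.null(o$spec) || is.null(o$out))
    config_error("simulate: --spec and --out are required")
  if (!file.exists(o$spec)) config_error("spec file not found: ", o$spec)
  sp <- jsonlite::read_json(o$spec, simplifyVector = TRUE)
  if (!is.null(o$seed)) sp$seed <- o$seed
  if (is.null(sp$seed)) config_error("simulate: seed is mandatory")
  dir.create(o$out, recursive = TRUE, showWarnings = FALSE)
  truth_path <- file.path(o$out, paste0(what, "_truth.json"))
  if (what == "calls") {
    probs <- independence_probs(sp$row_marginals, unlist(sp$col_marginal),
                                sp$multipliers)
    tab <- simulate_call_table(sp$n_genes, sp$factors, probs, sp$seed)
    write_call_table(tab, file.path(o$out, "calls.tsv"))
    jsonlite::write_json(attr(tab, "truth"), truth_path,
                         auto_unbox = TRUE, digits = NA)
  } else if (what == "clusters") {
    tab <- plant_clusters(unlist(sp$sizes), unlist(sp$single_sizes),
                          n_background = if (is.null(sp$n_background)) 0
                                         else sp$n_background,
                          seed = sp$seed)
    write_call_table(tab, file.path(o$out, "calls.tsv"))
    jsonlite::write_json(attr(tab, "truth"), truth_path, auto_unbox = TRUE)
  } else if (what == "promoters") {
    sim <- simulate_promoters(sp$n_fg, sp$n_bg,
                              length = if (is.null(sp$length)) 500 else sp$length,
                              gc = if (is.null(sp$gc)) 0.36 else sp$gc,
                              motif = sp$motif,
                              fg_presence = if (is.null(sp$fg_presence)) 0
                                            else sp$fg_presence,
                              bg_presence = if (is.null(sp$bg_presence)) 0
                                            else sp$bg_presence,
                              seed = sp$seed)
    write_promoters(sim$fg, file.path(o$out, "fg.fa"))
    write_promoters(sim$bg, file.path(o$out, "bg.fa"))
    jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE)
  } else if (what == "annotations") {
    ann <- simulate_annotations(sp$universe, sp$set, unlist(sp$bg_freq),
                                if (is.null(sp$enrich)) NULL
                                else unlist(sp$enrich), seed = sp$seed)
    data.table::fwrite(ann$pairs, file.path(o$out, "annotations.tsv"),
                       sep = "\t", quote = FALSE)
    jsonlite::write_json(attr(ann, "truth"), truth_path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    changes <- stats::setNames(unlist(sp$signature$change),
                               unlist(sp$signature$gene))
    sig <- build_signature(changes, n_top = sp$n_top)
    panel <- simulate_panel(sig, sp$n_experiments,
                            noise_sd = sp$noise_sd, seed = sp$seed)
    write_panel(panel, file.path(o$out, "panel.tsv"))
    jsonlite::write_json(list(noise_sd = attr(panel, "truth")), truth_path,
                         auto_unbox = TRUE, digits = NA)
  }
}

#' Command-line entry point
#'
#' Subcommands: `run-all --config cfg.json [--out dir] [--seed N]`;
#' `crosstab --calls t.tsv --rows EDE,U73 --col SA --out dir`;
#' `cluster --calls t.tsv --inhibitors EDE,U73 --out dir [--modifier R59]`;
#' `enrich --genes g.txt --annotation a.tsv --out dir`;
#' `scan --fg fg.fa --bg bg.fa --out dir [--catalog c.tsv]`;
#' `rank --panel p.tsv --changes c.tsv --out dir`;
#' `simulate calls|clusters|promoters|annotations|panel --spec s.json
#' --out dir [--seed N]`. Installed wrapper: `inst/cli/respmode.R`.
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly: 0 ok, 1 configuration error,
#'   2 runtime error.
#' @export
respmode_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: respmode <run-all|crosstab|cluster|enrich|scan|rank|simulate>",
    "[options]; see ?respmode_main")
  if (length(args) == 0L || args[1L] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(0L))
  }
  sub <- args[1L]
  rest <- args[-1L]
  status <- tryCatch({
    switch(sub,
      "run-all" = {
        o <- .cli_opts(rest, .opt("config"), .opt("out"),
                       .opt("seed", "integer", NULL))
        if (is.null(o$config)) config_error("--config is required")
        cfg <- read_run_config(o$config)
        if (!is.null(o$seed)) cfg$seed <- o$seed
        run_all(cfg, out_dir = if (is.null(o$out)) cfg$out_dir else o$out)
      },
      "crosstab" = .cli_crosstab(rest),
      "cluster" = .cli_cluster(rest),
      "enrich" = .cli_enrich(rest),
      "scan" = .cli_scan(rest),
      "rank" = .cli_rank(rest),
      "simulate" = .cli_simulate(rest),
      config_error("unknown subcommand: ", sub))
    0L
  }, respmode_config_error = function(e) {
    message("config error: ", conditionMessage(e)); 1L
  }, error = function(e) {
    message("error: ", conditionMessage(e)); 2L
  })
  invisible(status)
}
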