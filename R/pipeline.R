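# End-to-end pipeline and subcommand CLI.  Config files are JSON; every
# run directory gets exactly one manifest recording command, parameters,
# resolved seed, input checksums, package version and timestamp, so a run
# can be reproduced byte-for-byte (timestamp aside).

required_config_keys <- c("fasta", "motifs", "orders", "seed")

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  miss <- setdiff(required_config_keys, names(config))
  if (length(miss) > 0L) stop("missing key: ", paste(miss, collapse = ", "))
  config$max_gap <- config$max_gap %||% 200L
  config$replicates <- config$replicates %||% 1000L
  config$expected_length <- config$expected_length %||% NULL
  config$sig_ref <- config$sig_ref %||% 240
  config$weights <- config$weights %||%
    list(sig = 1, abc = 1, position = 1, coverage = 1, orientation = 1)
  config
}

parse_orders <- function(orders) {
  # "RRPE-PAC" strings or list of 2-vectors
  lapply(orders, function(o) {
    if (length(o) == 2L) return(as.character(o))
    parts <- strsplit(o, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("bad order spec: ", o)
    parts
  })
}

write_manifest <- function(out_dir, command, params, seed, inputs) {
  existing <- Filter(file.exists, inputs)
  manifest <- list(
    command = command,
    parameters = params,
    seed = seed,
    input_checksums = as.list(tools::md5sum(unlist(existing))),
    tool_version = as.character(utils::packageVersion("modulescout")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the full scan - modules - score - quartiles pipeline
#'
#' Executes the stages in order, fails fast on the first error, logs stage
#' timings and record counts, and writes `occ.tsv`, `modules.tsv`,
#' `attrs.tsv`, `q.tsv` plus a `manifest.json` into `out_dir`.
#'
#' @param config Path to a JSON config file or an equivalent list.
#'   Required keys: `fasta` (upstream FASTA path), `motifs` (motif TSV /
#'   JSON path or inline mapping), `orders` (character vector like
#'   `"RRPE-PAC"`), `seed`.  Optional: `max_gap` (200), `replicates`
#'   (1000), `weights`, `sig_ref` (240), `background` (FASTA path),
#'   `expected_length`, `groups` (gene-set grouping, see
#'   [aggregate_group_attributes()]).
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(label, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    message(sprintf("[%s] %.2fs%s", label,
                    proc.time()[["elapsed"]] - t0,
                    if (is.data.frame(res)) paste0(" (", nrow(res), " rows)")
                    else ""))
    res
  }
  regions <- stage("read", read_upstream_fasta(cfg$fasta,
                                               cfg$expected_length))
  motifs <- stage("motifs", load_motif_definitions(cfg$motifs))
  background <- if (!is.null(cfg$background))
    read_upstream_fasta(cfg$background) else NULL
  occ <- stage("scan", scan_regions(regions, motifs))
  write_occurrences(occ, file.path(out_dir, "occ.tsv"))
  orders <- parse_orders(cfg$orders)
  modules <- stage("modules",
                   discover_modules(occ, orders, regions, cfg$max_gap))
  write_modules(modules, file.path(out_dir, "modules.tsv"))
  weights <- do.call(score_weights, as.list(cfg$weights))
  attrs <- stage("score", {
    rows <- lapply(seq_along(orders), function(i) {
      score_module(regions, occ, orders[[i]], motifs,
                   max_gap = cfg$max_gap, R = cfg$replicates,
                   seed = cfg$seed + i, background = background,
                   weights = weights, sig_ref = cfg$sig_ref)
    })
    do.call(rbind, rows)
  })
  utils::write.table(attrs, file.path(out_dir, "attrs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  q <- stage("quartiles", {
    L <- max(region_lengths(regions))
    rows <- lapply(unique(occ$motif), function(m) {
      fr <- quartile_fractions(occ[occ$motif == m, , drop = FALSE], L = L)
      data.frame(motif = m, bin = names(fr), fraction = as.numeric(fr),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  utils::write.table(q, file.path(out_dir, "q.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "run", cfg[setdiff(names(cfg), "motifs")],
                 cfg$seed,
                 c(cfg$fasta, if (is.character(cfg$motifs)) cfg$motifs,
                   cfg$background))
  invisible(out_dir)
}

cli_usage <- function() {
  paste(
    "usage: modulescout <subcommand> [--key value ...]",
    "",
    "subcommands:",
    "  scan        --fasta F --motifs M --out occ.tsv",
    "  modules     --occ occ.tsv --fasta F --pair A,B [--max-gap 200] --out m.tsv",
    "  score       --fasta F --occ occ.tsv --motifs M --order A,B",
    "              [--background B] [--replicates 1000] [--seed S] --out a.tsv",
    "  quartiles   --occ occ.tsv [--L 800] --out q.tsv",
    "  aggregate   --attrs a.tsv --groups g.tsv --out agg.tsv",
    "  partition   --modules m.tsv --orders A-B,B-A --out p.tsv",
    "  enrich      --subset s.txt --universe u.txt --annot ann.tsv",
    "              [--alpha 1e-3] --out e.tsv",
    "  extra-genes --set set.fasta --candidates cand.fasta --motifs M",
    "              --motif NAME [--max-added 20] --out x.tsv",
    "  simulate    --spec spec.json --out-prefix sim/",
    "  run         --config config.json --out DIR",
    sep = "\n")
}

parse_cli_args <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--")) stop("unexpected argument: ", key)
    if (i == length(args)) stop("missing value for ", key)
    opts[[substring(key, 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

need <- function(opts, key) {
  v <- opts[[key]]
  if (is.null(v)) stop("missing required option --", key)
  v
}

#' Command line entry point
#'
#' Subcommand interface over the pipeline stages (see the package
#' vignette).  Designed to be wrapped by an Rscript launcher; returns the
#' exit status instead of quitting so it is testable in-process.
#'
#' @param args Character vector of command line arguments (defaults to the
#'   process arguments).
#' @return Integer exit status, invisibly (0 on success).
#' @export
ms_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L || args[1] %in% c("-h", "--help", "help")) {
      cat(cli_usage(), "\n")
      return(invisible(0L))
    }
    sub <- args[1]
    rest <- args[-1]
    if (length(rest) > 0L && rest[1] %in% c("-h", "--help")) {
      cat(cli_usage(), "\n")
      return(invisible(0L))
    }
    opts <- parse_cli_args(rest)
    switch(sub,
      scan = cli_scan(opts),
      modules = cli_modules(opts),
      score = cli_score(opts),
      quartiles = cli_quartiles(opts),
      aggregate = cli_aggregate(opts),
      partition = cli_partition(opts),
      enrich = cli_enrich(opts),
      `extra-genes` = cli_extra_genes(opts),
      simulate = cli_simulate(opts),
      run = {
        run_pipeline(need(opts, "config"), need(opts, "out"))
        0L
      },
      stop("unknown subcommand: ", sub))
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}

cli_scan <- function(opts) {
  regions <- read_upstream_fasta(need(opts, "fasta"))
  motifs <- load_motif_definitions(need(opts, "motifs"))
  write_occurrences(scan_regions(regions, motifs), need(opts, "out"))
  0L
}

cli_modules <- function(opts) {
  occ <- read_occurrences(need(opts, "occ"))
  regions <- read_upstream_fasta(need(opts, "fasta"))
  pair <- strsplit(need(opts, "pair"), ",", fixed = TRUE)[[1]]
  max_gap <- as.integer(opts$`max-gap` %||% 200L)
  write_modules(discover_modules(occ, list(pair), regions, max_gap),
                need(opts, "out"))
  0L
}

cli_score <- function(opts) {
  regions <- read_upstream_fasta(need(opts, "fasta"))
  occ <- read_occurrences(need(opts, "occ"))
  motifs <- load_motif_definitions(need(opts, "motifs"))
  order <- strsplit(need(opts, "order"), ",", fixed = TRUE)[[1]]
  background <- if (!is.null(opts$background))
    read_upstream_fasta(opts$background) else NULL
  attrs <- score_module(
    regions, occ, order, motifs,
    max_gap = as.integer(opts$`max-gap` %||% 200L),
    R = as.integer(opts$replicates %||% 1000L),
    seed = if (!is.null(opts$seed)) as.integer(opts$seed) else NULL,
    background = background)
  utils::write.table(attrs, need(opts, "out"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  0L
}

cli_quartiles <- function(opts) {
  occ <- read_occurrences(need(opts, "occ"))
  L <- as.integer(opts$L %||% 800L)
  rows <- lapply(unique(occ$motif), function(m) {
    fr <- quartile_fractions(occ[occ$motif == m, , drop = FALSE], L = L)
    data.frame(motif = m, bin = names(fr), fraction = as.numeric(fr))
  })
  utils::write.table(do.call(rbind, rows), need(opts, "out"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  0L
}

cli_aggregate <- function(opts) {
  attrs <- utils::read.delim(need(opts, "attrs"), stringsAsFactors = FALSE)
  groups <- utils::read.delim(need(opts, "groups"), stringsAsFactors = FALSE)
  if (!all(c("gene_set", "group") %in% names(groups))) {
    stop("groups TSV must have columns: gene_set, group")
  }
  grouping <- stats::setNames(groups$group, groups$gene_set)
  agg <- aggregate_group_attributes(attrs, grouping)
  utils::write.table(agg, need(opts, "out"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  0L
}

cli_partition <- function(opts) {
  modules <- read_modules(need(opts, "modules"))
  orders <- strsplit(need(opts, "orders"), ",", fixed = TRUE)[[1]]
  if (length(orders) != 2L) stop("--orders needs two comma-separated labels")
  part <- partition_by_orientation(modules, orders[1], orders[2])
  out <- rbind(
    data.frame(gene_id = part$subset1, subset = orders[1]),
    data.frame(gene_id = part$subset2, subset = orders[2]),
    data.frame(gene_id = part$excluded,
               subset = rep("excluded", length(part$excluded))))
  utils::write.table(out, need(opts, "out"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  0L
}

cli_enrich <- function(opts) {
  subset <- readLines(need(opts, "subset"))
  universe <- readLines(need(opts, "universe"))
  ann <- read_annotations(need(opts, "annot"))
  res <- hypergeometric_enrichment(subset, universe, ann,
                                   alpha = as.numeric(opts$alpha %||% 1e-3))
  utils::write.table(res, need(opts, "out"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  0L
}

cli_extra_genes <- function(opts) {
  set_regions <- read_upstream_fasta(need(opts, "set"))
  cand <- read_upstream_fasta(need(opts, "candidates"))
  motifs <- load_motif_definitions(need(opts, "motifs"))
  res <- extra_gene_search(set_regions, cand, motifs,
                           name = need(opts, "motif"),
                           max_added = as.integer(opts$`max-added` %||% 20L))
  utils::write.table(res, need(opts, "out"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  0L
}

cli_simulate <- function(opts) {
  spec_cfg <- jsonlite::read_json(need(opts, "spec"), simplifyVector = TRUE)
  prefix <- need(opts, "out-prefix")
  dir.create(dirname(file.path(prefix, ".")), showWarnings = FALSE,
             recursive = TRUE)
  args <- spec_cfg
  if (!is.null(args$order)) args$order <- as.character(args$order)
  if (!is.null(args$motifs)) {
    args$motifs <- load_motif_definitions(args$motifs)
  }
  if (!is.null(args$gap)) args$gap <- as.list(args$gap)
  spec <- do.call(plant_spec, args)
  ds <- generate_dataset(spec)
  write_upstream_fasta(ds$regions, file.path(prefix, "regions.fasta"))
  write_occurrences(ds$occurrences, file.path(prefix, "truth_occ.tsv"))
  write_modules(ds$modules, file.path(prefix, "truth_modules.tsv"))
  echo <- unclass(ds$spec)
  echo$motifs <- stats::setNames(as.list(ds$spec$motifs$consensus),
                                 ds$spec$motifs$name)
  jsonlite::write_json(echo, file.path(prefix, "spec.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  0L
}
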