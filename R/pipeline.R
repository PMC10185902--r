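# End-to-end orchestration and the consistency validator.

#' Run the full screen on files or in-memory objects
#'
#' Pipeline: read VCF -> genotype matrices (SNP+InDel for calling, InDel-only
#' for screening) -> haplogroup assignment -> clade-exactness screen ->
#' dedup -> outputs. When \code{out_dir} is given, writes
#' \code{candidates.tsv}, \code{frequencies.tsv}, \code{calls.tsv} and
#' \code{summary.json}; partial outputs are removed if any stage fails.
#'
#' @param vcf VCF path or a \code{vcf_table}.
#' @param tree Newick path/text or an \code{hg_tree} (markers already
#'   attached).
#' @param markers marker index TSV path or data.frame; ignored when
#'   \code{tree} is an \code{hg_tree}.
#' @param known optional known-marker TSV path or data.frame for dedup.
#' @param out_dir optional output directory.
#' @param focal,min_call_fraction,strict_missing see
#'   \code{\link{screen_config}}.
#' @param mask optional BED path or \code{GRanges} of regions to exclude.
#' @param min_support caller branch-support threshold
#'   (\code{\link{assign_all}}).
#' @return invisibly, a list: \code{summary} (stage counters, per-clade
#'   tally, config), \code{result} (\code{screen_result}), \code{calls},
#'   \code{frequencies}, \code{tree}, \code{matrix} (the InDel matrix).
#' @export
run_screen <- function(vcf, tree, markers = NULL, known = NULL, out_dir = NULL,
                       focal = "O", min_call_fraction = 0.9,
                       strict_missing = FALSE, mask = NULL, min_support = 0.5) {
  if (!inherits(tree, "hg_tree")) tree <- parse_haplogroup_tree(tree, markers)
  if (is.character(known)) known <- read_marker_table(known)
  vt <- if (inherits(vcf, "vcf_table")) vcf else read_vcf_table(vcf)
  config <- screen_config(focal, min_call_fraction, strict_missing)

  marker_gm <- build_genotype_matrix(vt, keep_class = c("snp", "biallelic_indel"),
                                     mask = mask)
  calls <- assign_all(marker_gm, tree, min_support)
  indel_gm <- build_genotype_matrix(vt, keep_class = "biallelic_indel", mask = mask)
  result <- screen_indels(indel_gm, calls, tree, config, known)
  freqs <- clade_frequencies(indel_gm, calls, tree)

  tally <- as.list(table(result$novel$assigned_clade))
  summary <- list(
    counters = as.list(result$counters),
    candidate_count = nrow(result$novel),
    per_clade = tally,
    config = list(focal_clade = config$focal_clade,
                  min_call_fraction = config$min_call_fraction,
                  strict_missing = config$strict_missing,
                  min_support = min_support),
    n_samples = length(vt$samples))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(out_dir, c("candidates.tsv", "frequencies.tsv",
                                  "calls.tsv", "summary.json"))
    tryCatch({
      utils::write.table(result$candidates, paths[1], sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(freqs, paths[2], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      write_calls(calls, paths[3])
      jsonlite::write_json(summary, paths[4], auto_unbox = TRUE, pretty = TRUE)
    }, error = function(e) {
      unlink(paths)
      stop(e)
    })
  }
  invisible(list(summary = summary, result = result, calls = calls,
                 frequencies = freqs, tree = tree, matrix = indel_gm))
}

#' Cross-check candidate states against haplogroup calls
#'
#' For every sample, the candidate InDels observed in derived state must be
#' exactly those whose assigned clade is an ancestor-or-self of the sample's
#' called node. Missing calls cannot conflict and are skipped.
#'
#' @param candidates candidate table (a \code{screen_result}, or its
#'   \code{candidates}/\code{novel} data.frame with \code{variant_key},
#'   \code{assigned_clade}, \code{orientation}).
#' @param gm the InDel \code{geno_matrix} the screen consumed.
#' @param calls calls table.
#' @param tree an \code{hg_tree}.
#' @return data.frame of conflicts: \code{sample}, \code{variant_key},
#'   \code{expected}, \code{observed} (zero rows when consistent).
#' @export
validate_consistency <- function(candidates, gm, calls, tree) {
  if (inherits(candidates, "screen_result")) candidates <- candidates$candidates
  empty <- data.frame(sample = character(), variant_key = character(),
                      expected = character(), observed = character(),
                      stringsAsFactors = FALSE)
  if (nrow(candidates) == 0) return(empty)
  node_of <- stats::setNames(calls$haplogroup, calls$sample)
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    key <- candidates$variant_key[i]
    at <- match(key, gm$variants$key)
    if (is.na(at))
      yis_contract_error("candidate %s absent from matrix; candidates must come from the same cohort", key)
    derived_code <- if (candidates$orientation[i] == "ALT") 1L else 0L
    v <- gm$calls[at, ]
    clade <- candidates$assigned_clade[i]
    for (s in calls$sample) {
      if (is.na(v[s])) next
      expected <- clade %in% tree_ancestors(tree, node_of[[s]])
      observed <- v[s] == derived_code
      if (expected != observed)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, variant_key = key,
          expected = if (expected) "derived" else "ancestral",
          observed = if (observed) "derived" else "ancestral",
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else empty
  yis_log("validate_consistency: %d conflict(s) over %d candidate(s) x %d sample(s)",
          nrow(out), nrow(candidates), nrow(calls))
  out
}

# ---- command-line interface -------------------------------------------------

cli_exit_code <- function(e) {
  if (inherits(e, "yis_parse_error")) 2L
  else if (inherits(e, c("yis_config_error", "yis_validate_error"))) 3L
  else if (inherits(e, "yis_contract_error")) 4L
  else if (inherits(e, "yis_format_error")) 5L
  else if (inherits(e, "yis_lookup_error")) 6L
  else 1L
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate}, \code{assign}, \code{screen},
#' \code{replay-table1}, \code{validate}. Results go to \code{--out-dir};
#' logs go to stderr. Exit codes: 0 success, 2 parse, 3 config/validation,
#' 4 contract, 5 format, 6 lookup, 1 other.
#'
#' @param args character vector of arguments (default: the command line).
#' @return integer exit status, invisibly.
#' @export
yis_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0)
      yis_config_error("usage: <simulate|assign|screen|replay-table1|validate> [options]")
    cmd <- args[1]
    rest <- args[-1]
    switch(cmd,
      "simulate" = cli_simulate(rest),
      "assign" = cli_assign(rest),
      "screen" = cli_screen(rest),
      "replay-table1" = cli_replay(rest),
      "validate" = cli_validate(rest),
      yis_config_error("unknown subcommand '%s'", cmd))
    0L
  }, yis_error = function(e) {
    message("ERROR: ", conditionMessage(e))
    cli_exit_code(e)
  }, error = function(e) {
    message("ERROR: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_common_opts <- function() {
  list(
    optparse::make_option("--vcf", type = "character"),
    optparse::make_option("--tree", type = "character"),
    optparse::make_option("--markers", type = "character"),
    optparse::make_option("--known", type = "character", default = NULL),
    optparse::make_option("--focal", type = "character", default = "O"),
    optparse::make_option("--min-call-fraction", dest = "min_call_fraction",
                          type = "double", default = 0.9),
    optparse::make_option("--strict-missing", dest = "strict_missing",
                          action = "store_true", default = FALSE),
    optparse::make_option("--mask", type = "character", default = NULL),
    optparse::make_option("--min-support", dest = "min_support",
                          type = "double", default = 0.5),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out-dir", dest = "out_dir", type = "character",
                          default = "."))
}

cli_parse <- function(args, extra = list()) {
  parser <- optparse::OptionParser(option_list = c(cli_common_opts(), extra))
  optparse::parse_args(parser, args = args)
}

require_opts <- function(opt, needed) {
  for (nm in needed)
    if (is.null(opt[[nm]]))
      yis_config_error("missing required option --%s", gsub("_", "-", nm))
}

cli_simulate <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--n-nodes", dest = "n_nodes", type = "integer",
                          default = 30L),
    optparse::make_option("--samples-per-node", dest = "spn", type = "integer",
                          default = 3L),
    optparse::make_option("--missing-rate", dest = "missing_rate",
                          type = "double", default = 0),
    optparse::make_option("--het-rate", dest = "het_rate", type = "double",
                          default = 0)))
  sim <- simulate_cohort(sim_config(n_focal_nodes = opt$n_nodes,
                                    samples_per_node = opt$spn,
                                    missing_rate = opt$missing_rate,
                                    het_rate = opt$het_rate, seed = opt$seed))
  write_sim_cohort(sim, opt$out_dir)
  yis_log("simulate: wrote cohort under %s", opt$out_dir)
}

cli_assign <- function(args) {
  opt <- cli_parse(args)
  require_opts(opt, c("vcf", "tree", "markers"))
  tree <- parse_haplogroup_tree(opt$tree, opt$markers)
  vt <- read_vcf_table(opt$vcf)
  gm <- build_genotype_matrix(vt, keep_class = c("snp", "biallelic_indel"),
                              mask = opt$mask)
  calls <- assign_all(gm, tree, opt$min_support)
  dir.create(opt$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_calls(calls, file.path(opt$out_dir, "calls.tsv"))
  yis_log("assign: wrote %s", file.path(opt$out_dir, "calls.tsv"))
}

cli_screen <- function(args) {
  opt <- cli_parse(args)
  require_opts(opt, c("vcf", "tree", "markers"))
  run_screen(opt$vcf, opt$tree, opt$markers, known = opt$known,
             out_dir = opt$out_dir, focal = opt$focal,
             min_call_fraction = opt$min_call_fraction,
             strict_missing = opt$strict_missing, mask = opt$mask,
             min_support = opt$min_support)
  yis_log("screen: outputs under %s", opt$out_dir)
}

cli_replay <- function(args) {
  opt <- cli_parse(args)
  sim <- table1_replay_fixture(seed = opt$seed)
  dir.create(opt$out_dir, showWarnings = FALSE, recursive = TRUE)
  vcf_path <- file.path(opt$out_dir, "replay.vcf")
  writeLines(sim$vcf, vcf_path)
  run_screen(vcf_path, sim$tree, known = sim$known, out_dir = opt$out_dir,
             focal = "O", min_call_fraction = opt$min_call_fraction,
             strict_missing = opt$strict_missing)
  yis_log("replay-table1: outputs under %s", opt$out_dir)
}

cli_validate <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--candidates", type = "character"),
    optparse::make_option("--calls", type = "character")))
  require_opts(opt, c("vcf", "tree", "markers", "candidates", "calls"))
  tree <- parse_haplogroup_tree(opt$tree, opt$markers)
  vt <- read_vcf_table(opt$vcf)
  gm <- build_genotype_matrix(vt, keep_class = "biallelic_indel", mask = opt$mask)
  candidates <- utils::read.delim(opt$candidates, stringsAsFactors = FALSE)
  calls <- utils::read.delim(opt$calls, colClasses = "character")
  conflicts <- validate_consistency(candidates, gm, calls, tree)
  dir.create(opt$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(conflicts, file.path(opt$out_dir, "conflicts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yis_log("validate: %d conflict(s); wrote %s", nrow(conflicts),
          file.path(opt$out_dir, "conflicts.tsv"))
}
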