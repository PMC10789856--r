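# End-to-end orchestration: alignment -> distances -> NJ -> rooting ->
# timing -> report, with every intermediate artifact written to disk and a
# self-describing log (thresholds, window, seed), so a report can be traced
# back to its exact configuration. Artifacts carry no timestamps: re-running
# an identical config reproduces them byte for byte.

#' Pipeline configuration
#'
#' All defaults are overridable; the config is a plain list and round-trips
#' through JSON losslessly.
#'
#' @param model default [substitution_model()] for alignment-mode cases.
#' @param bootstrap_replicates bootstrap replicate count (default 500).
#' @param thresholds [timing_thresholds()] for classification.
#' @param synteny_window neighbourhood window (genes each side, default 10).
#' @param epsilon orthology ambiguity margin (default 0.05).
#' @param seed integer seed for any stochastic stage.
#' @param out_dir artifact directory (`NULL` = no artifacts written).
#' @export
run_config <- function(model = substitution_model("poisson"),
                       bootstrap_replicates = 500,
                       thresholds = timing_thresholds(),
                       synteny_window = 10, epsilon = 0.05,
                       seed = NULL, out_dir = NULL) {
  stopifnot(bootstrap_replicates >= 1, synteny_window >= 1, epsilon >= 0)
  structure(list(model = model, bootstrap_replicates = bootstrap_replicates,
                 thresholds = thresholds, synteny_window = synteny_window,
                 epsilon = epsilon, seed = seed, out_dir = out_dir),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the timing pipeline
#'
#' Tree mode (`tree` / `tree_file` given) skips the distance and NJ stages
#' and is exactly equivalent to feeding the alignment-mode tree back in.
#'
#' @param config a [run_config()].
#' @param alignment an [alignment()], or `alignment_file` a FASTA path.
#' @param tree an [ape::phylo], or `tree_file` a Newick path.
#' @param labeling a [paralog_labeling()].
#' @param alignment_file,tree_file file-path alternatives to the objects.
#' @param molecule molecule type for `alignment_file` (default protein).
#' @param name case name used in the report.
#' @param outgroups optional list of outgroup configurations.
#' @return the [timing_report()] data frame, invisibly; artifacts (distance
#'   matrix, tree, TSV/JSON report, log) are written to `config$out_dir`
#'   when set.
#' @export
run_timing_pipeline <- function(config, labeling, alignment = NULL,
                                tree = NULL, alignment_file = NULL,
                                tree_file = NULL, molecule = "protein",
                                name = "case", outgroups = NULL) {
  stopifnot(inherits(config, "run_config"), inherits(labeling, "paralog_labeling"))
  log_lines <- c("ohnotime timing pipeline",
                 sprintf("thresholds: ancient >= %g, recent <= %g",
                         config$thresholds$ancient, config$thresholds$recent),
                 sprintf("seed: %s", config$seed %||% "none"))
  if (!is.null(alignment_file)) {
    alignment <- stage("io", read_fasta(alignment_file, molecule))
  }
  if (!is.null(tree_file)) tree <- stage("io", read_newick(tree_file))
  if (is.null(tree) && is.null(alignment)) {
    stop("stage 'io': supply a tree or an alignment")
  }
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dm <- NULL
  if (is.null(tree)) {
    if (inherits(alignment, "seq_set") && !inherits(alignment, "alignment")) {
      alignment <- stage("io", alignment(alignment))
    }
    dm <- stage("distances", distance_matrix(alignment, config$model))
    log_lines <- c(log_lines, sprintf("distances: model %s, %d taxa",
                                      config$model$name, length(dm$labels)))
    tree <- stage("njtree", neighbor_joining(dm))
    if (!is.null(out)) {
      write_distance_matrix(dm, file.path(out, "distances.tsv"), "tsv")
      write_distance_matrix(dm, file.path(out, "distances.phy"), "phylip")
    }
  } else {
    log_lines <- c(log_lines, "tree mode: distance and NJ stages skipped")
  }
  if (!is.null(out)) write_newick(tree, precision = 10,
                                  path = file.path(out, "tree.nwk"))
  cases <- list(list(name = name, tree = tree, labeling = labeling,
                     molecule = molecule, outgroups = outgroups))
  report <- stage("timing", timing_report(cases, config))
  bad <- report$note[!is.na(report$note)]
  if (length(bad)) log_lines <- c(log_lines, paste("note:", bad))
  if (!is.null(out)) {
    utils::write.table(report, file.path(out, "timing_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out, "timing_report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(log_lines, file.path(out, "log.txt"))
  }
  invisible(report)
}

#' Run the synteny pipeline
#'
#' @param config a [run_config()].
#' @param queries,references neighbourhood-table paths (or TSV text) for the
#'   query and reference genomes.
#' @param synonym_map optional two-column TSV (`symbol`, `canonical`) path or
#'   named character vector.
#' @return list with the [synteny_matrix()], the [find_diagnostic_neighbors()]
#'   witness sets, and the [assign_orthologs()] result; artifacts
#'   (`synteny_matrix.tsv`, `assignment.json`) under `config$out_dir`.
#' @export
run_synteny_pipeline <- function(config, queries, references, synonym_map = NULL) {
  stopifnot(inherits(config, "run_config"))
  q <- stage("io", if (is.character(queries)) read_neighborhood_table(queries)
             else queries)
  r <- stage("io", if (is.character(references)) read_neighborhood_table(references)
             else references)
  if (is.character(synonym_map) && length(synonym_map) == 1 &&
      file.exists(synonym_map)) {
    tab <- utils::read.delim(synonym_map, header = TRUE,
                             stringsAsFactors = FALSE)
    synonym_map <- stats::setNames(tab[[2]], tab[[1]])
  }
  sm <- stage("synteny",
              synteny_matrix(q, r, window = config$synteny_window,
                             synonym_map = synonym_map))
  witnesses <- stage("synteny",
                     find_diagnostic_neighbors(r, window = config$synteny_window,
                                               synonym_map = synonym_map))
  asg <- stage("synteny", assign_orthologs(sm, epsilon = config$epsilon))
  out <- config$out_dir
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(cbind(query = rownames(sm$jaccard), round(sm$jaccard, 6)),
                       file.path(out, "synteny_matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(mapping = as.list(asg$mapping), score = asg$score,
           ambiguous = asg$ambiguous,
           witnesses = witnesses),
      file.path(out, "assignment.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  list(matrix = sm, witnesses = witnesses, assignment = asg)
}
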