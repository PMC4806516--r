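#' Pipeline run configuration
#'
#' Validated bundle of everything one end-to-end run needs; fully serialized
#' into the run report for reproducibility.
#'
#' @param alignment path to the input alignment.
#' @param format `"auto"`, `"fasta"` or `"phylip"`.
#' @param freq_mode `"empirical"` or `"ml_estimated"` base frequencies.
#' @param seeds integer vector; one full run per seed (starting tree and all
#'   downstream searches).
#' @param workers worker count for the model scan.
#' @param criteria criterion subset (default all five).
#' @param out output directory (created if missing).
#' @param include_branch_lengths count branch lengths among the degrees of
#'   freedom entering the criteria.
#' @param control optimizer control overrides.
#' @return a `run_config`.
#' @export
run_config <- function(alignment, format = "auto",
                       freq_mode = c("empirical", "ml_estimated"),
                       seeds = 1L, workers = 1L,
                       criteria = CRITERION_NAMES,
                       out = "gtrspace_run",
                       include_branch_lengths = TRUE,
                       control = list()) {
  freq_mode <- match.arg(freq_mode)
  if (!file.exists(alignment))
    stop("alignment file not found: ", alignment, call. = FALSE)
  if (!format %in% c("auto", "fasta", "phylip"))
    stop("unknown format '", format, "'", call. = FALSE)
  criterion_specs(criteria)
  if (length(seeds) < 1L || anyNA(suppressWarnings(as.integer(seeds))))
    stop("seeds must be integers", call. = FALSE)
  if (workers < 1L) stop("workers must be >= 1", call. = FALSE)
  control$include_branch_lengths <- include_branch_lengths
  structure(list(alignment = alignment, format = format,
                 freq_mode = freq_mode, seeds = as.integer(seeds),
                 workers = as.integer(workers), criteria = criteria,
                 out = out,
                 include_branch_lengths = include_branch_lengths,
                 control = control),
            class = "run_config")
}

#' Run the full model-test pipeline
#'
#' For each seed: parse the alignment, build the randomized stepwise-addition
#' parsimony starting tree, score all 203 models on it, pick the per-criterion
#' winners, run one ML tree search per distinct winning model (criteria that
#' agree on a model share a search) plus a GTR+Gamma baseline search, and
#' write per-criterion Newick trees, the 203-row score table (TSV), a winners
#' summary (JSON) and the pairwise rRF matrix of the final trees.
#'
#' @param config a `run_config`.
#' @return (invisibly) a list with per-seed results: `winners`, `fits`,
#'   `score_table`, `trees`, `rrf`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  aln <- read_alignment(config$alignment, config$format)
  message("parsed alignment: ", length(aln$taxa), " taxa x ", aln$n_sites,
          " sites (", ncol(aln$masks), " patterns)")
  runs <- list()

  for (seed in config$seeds) {
    tag <- paste0("seed", seed)
    run_dir <- file.path(config$out, tag)
    dir.create(file.path(run_dir, "trees"), showWarnings = FALSE,
               recursive = TRUE)
    message("[", tag, "] stepwise-addition parsimony starting tree")
    start <- parsimony_start_tree(aln, seed)

    message("[", tag, "] scoring all models on the fixed tree")
    ev <- evaluate_all_models(aln, start, config$freq_mode,
                              workers = config$workers,
                              criteria = config$criteria,
                              control = config$control)
    write_score_table(ev$table, file.path(run_dir, "score_table.tsv"))

    winners <- vapply(config$criteria, function(cn)
      ev$results$entries[[cn]]$best_model, character(1))
    distinct <- unique(c(winners, "123456"))
    message("[", tag, "] winners: ",
            paste(config$criteria, winners, sep = "=", collapse = " "),
            "; running ", length(distinct), " tree search(es)")
    fits <- stats::setNames(lapply(distinct, function(ms)
      ml_search(start, aln, ms, config$freq_mode, config$control)), distinct)

    trees <- c(stats::setNames(
      lapply(config$criteria, function(cn) fits[[winners[[cn]]]]$tree),
      config$criteria),
      list("GTR+G" = fits[["123456"]]$tree))
    for (nm in names(trees))
      write_newick(trees[[nm]],
                   file.path(run_dir, "trees",
                             paste0(gsub("[^A-Za-z0-9]+", "_", nm), ".nwk")))

    rrf <- rrf_matrix(trees, names(trees))
    utils::write.table(rrf, file.path(run_dir, "rrf_matrix.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)

    summary <- list(
      config = config[c("alignment", "format", "freq_mode", "criteria",
                        "workers", "include_branch_lengths")],
      seed = seed,
      n_taxa = length(aln$taxa), n_sites = aln$n_sites,
      winners = as.list(winners),
      search_lnL = lapply(fits, function(f) f$logLik),
      parsimony_score = fitch_score(start, aln))
    jsonlite::write_json(summary, file.path(run_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    runs[[tag]] <- list(winners = winners, fits = fits,
                        score_table = ev$table, trees = trees, rrf = rrf,
                        start_tree = start)
  }
  invisible(runs)
}
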