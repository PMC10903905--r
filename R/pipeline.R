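# Pipeline orchestration: filter -> discover -> classify -> summarize,
# driven by a single run configuration (optionally read from YAML).
# Stage progress is logged to standard error as machine-parseable
# key=value lines; partial outputs are removed on failure.

.CONFIG_SECTIONS <- c("input", "filter", "discovery", "precedence", "output")
.INPUT_KEYS <- c("fasta", "counts", "meta", "refs_fasta", "refs_annot",
                 "prior", "mode")
.OUTPUT_KEYS <- c("dir")

.check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop("unknown configuration key(s) in ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
}

#' Read and validate a pipeline run configuration from YAML
#'
#' Recognized sections: `input` (`fasta`, `counts`, `meta`, optional
#' `refs_fasta`, `refs_annot`, `prior`, `mode`), `filter`, `discovery`,
#' `precedence` (arguments of the respective `*_config()` constructors)
#' and `output` (`dir`). Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config A configuration list built in R.
#' @export
validate_run_config <- function(config) {
  .check_keys(config, .CONFIG_SECTIONS, "run config")
  if (is.null(config$input) || is.null(config$output)) {
    stop("run config needs 'input' and 'output' sections")
  }
  .check_keys(config$input, .INPUT_KEYS, "input")
  .check_keys(config$output, .OUTPUT_KEYS, "output")
  .check_keys(config$filter, names(formals(filter_config)), "filter")
  .check_keys(config$discovery, names(formals(discovery_config)), "discovery")
  .check_keys(config$precedence, names(formals(precedence_config)), "precedence")
  for (key in c("fasta", "counts", "meta")) {
    if (is.null(config$input[[key]])) stop("input section needs '", key, "'")
  }
  config
}

.input_error <- function(msg) {
  stop(structure(class = c("foramsig_input_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.stage_error <- function(stage, e, outputs) {
  unlink(outputs[file.exists(outputs)])
  stop(structure(class = c("foramsig_stage_error", "error", "condition"),
                 list(message = sprintf("stage '%s' failed: %s",
                                        stage, conditionMessage(e)),
                      call = NULL)))
}

.log_kv <- function(stage, ...) {
  kv <- c(...)
  message(paste(c(sprintf("stage=%s", stage),
                  sprintf("%s=%s", names(kv), kv)), collapse = " "))
}

#' Run the full classification pipeline
#'
#' Executes filter, discover, classify and summarize in order, writing
#' each stage's artifacts under `config$output$dir`: the kept sequences
#' (`kept.fasta`, `kept.tsv`), the screen log (`screen_log.tsv`), the
#' signature table (`signatures.tsv`), assignments and composition
#' (`assignments.tsv`, `composition.tsv`), and the biogeography tables
#' (`lineage_by_area.tsv`, `presence.tsv`, `upset.tsv`). Input problems
#' raise a `foramsig_input_error`; failures inside a stage remove that
#' stage's partial outputs and raise a `foramsig_stage_error`.
#'
#' @param config Configuration list (see [read_run_config()]), or a path
#'   to a YAML file.
#' @return Invisibly, a list with the output paths and per-stage counts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  inp <- config$input
  paths <- unlist(inp[intersect(names(inp), c("fasta", "counts", "meta",
                                              "refs_fasta", "refs_annot", "prior"))])
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    .input_error(paste("missing input file(s):", paste(missing, collapse = ", ")))
  }
  out_dir <- config$output$dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fcfg <- do.call(filter_config, as.list(config$filter))
  dcfg <- do.call(discovery_config, as.list(config$discovery))
  pcfg <- do.call(precedence_config, as.list(config$precedence))
  mode <- if (is.null(inp$mode)) "one_region" else inp$mode

  out <- function(f) file.path(out_dir, f)

  # load
  ds <- tryCatch({
    refs <- if (!is.null(inp$refs_fasta)) {
      load_references(inp$refs_fasta, inp$refs_annot)
    } else NULL
    list(data = load_dataset(inp$fasta, inp$counts, inp$meta), refs = refs)
  }, error = function(e) .stage_error("load", e, character(0)))
  refs <- ds$refs
  ds <- ds$data
  .log_kv("load", n_otus = nrow(ds$otus), n_samples = ncol(ds$counts),
          n_refs = if (is.null(refs)) 0 else nrow(refs))

  # filter
  stage_out <- c(out("kept.fasta"), out("kept.tsv"), out("screen_log.tsv"))
  sc <- tryCatch({
    sc <- screen_dataset(ds, fcfg, mode, refs)
    write_fasta(setNames(sc$kept$sequence, sc$kept$otu_id), stage_out[1])
    .write_tsv(sc$kept[, setdiff(names(sc$kept), "sequence")], stage_out[2])
    .write_tsv(sc$log, stage_out[3])
    sc
  }, error = function(e) .stage_error("filter", e, stage_out))
  .log_kv("filter", n_in = nrow(ds$otus), n_kept = nrow(sc$kept),
          n_discarded = nrow(ds$otus) - nrow(sc$kept))

  # discover
  stage_out <- out("signatures.tsv")
  signatures <- tryCatch({
    cores <- extract_cores(sc$kept, on_empty = "drop")
    sig <- discover_signatures(cores, refs, dcfg)
    sig <- name_lineages(sig, dcfg)
    write_signatures(sig, stage_out)
    sig
  }, error = function(e) .stage_error("discover", e, stage_out))
  .log_kv("discover", n_cores = nrow(sc$kept), n_signatures = nrow(signatures))

  # classify
  stage_out <- c(out("assignments.tsv"), out("composition.tsv"))
  combined <- tryCatch({
    asg <- match_signatures(signatures, ds)
    if (!is.null(inp$prior)) {
      prior <- read_prior_assignments(inp$prior)
      asg <- merge_with_prior(prior, asg, pcfg)
    }
    write_assignments(asg, stage_out[1])
    .write_tsv(composition_summary(asg, ds), stage_out[2])
    asg
  }, error = function(e) .stage_error("classify", e, stage_out))
  .log_kv("classify", n_assigned = sum(combined$label != "unassigned"),
          n_unassigned = sum(combined$label == "unassigned"))

  # summarize
  stage_out <- c(out("lineage_by_area.tsv"), out("presence.tsv"), out("upset.tsv"))
  tryCatch({
    alm <- lineage_by_area(combined, ds)
    m <- data.frame(lineage = rownames(alm$reads), alm$reads,
                    check.names = FALSE, stringsAsFactors = FALSE)
    .write_tsv(m, stage_out[1])
    pa <- presence_absence(alm)
    .write_tsv(data.frame(lineage = rownames(pa), pa, check.names = FALSE),
               stage_out[2])
    sets <- shared_otu_sets(combined, ds)
    .write_tsv(sets$upset, stage_out[3])
  }, error = function(e) .stage_error("summarize", e, stage_out))
  .log_kv("summarize", n_lineages = nrow(lineage_by_area(combined, ds)$reads),
          n_areas = length(unique(ds$samples$area)))

  invisible(list(
    outputs = c(kept_fasta = out("kept.fasta"), kept = out("kept.tsv"),
                screen_log = out("screen_log.tsv"),
                signatures = out("signatures.tsv"),
                assignments = out("assignments.tsv"),
                composition = out("composition.tsv"),
                lineage_by_area = out("lineage_by_area.tsv"),
                presence = out("presence.tsv"), upset = out("upset.tsv")),
    n_kept = nrow(sc$kept),
    n_signatures = nrow(signatures),
    n_assigned = sum(combined$label != "unassigned")))
}
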