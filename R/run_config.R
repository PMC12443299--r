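#' Assemble a validated run configuration
#'
#' One structure drives the command-style entry points: input location and
#' quarters, the target ingredient, vocabulary paths, thresholds, BCPNN
#' priors, the EBGM lower-bound multiplier, output directory, seed (for
#' synthetic runs) and the behavioral flags (continuity correction,
#' outcome-precedence mode, within-case PT de-duplication).
#'
#' @param input_dir Directory with quarterly files (and, by default, the
#'   vocabulary files).
#' @param quarters Character vector of quarter labels.
#' @param target Canonical target ingredient.
#' @param drug_file,meddra_file Vocabulary file paths.
#' @param out_dir Output directory for reports.
#' @param thresholds [signal_thresholds()].
#' @param priors [bcpnn_priors()].
#' @param ebgm_z EBGM lower-bound multiplier.
#' @param seed Seed for synthetic generation runs.
#' @param synthetic `NULL` or a list of [synthetic_config()] arguments for
#'   `run_generate()`.
#' @param haldane,ps_only,dedup_within_case,outcome_mode Behavior flags.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_dir = ".", quarters = "24Q3",
                       target = "DRUG_0001",
                       drug_file = file.path(input_dir, "drug_dictionary.tsv"),
                       meddra_file = file.path(input_dir, "pt_soc_map.tsv"),
                       out_dir = "signal_out",
                       thresholds = signal_thresholds(),
                       priors = bcpnn_priors(), ebgm_z = 1.645,
                       seed = 1L, synthetic = NULL, haldane = FALSE,
                       ps_only = TRUE, dedup_within_case = TRUE,
                       outcome_mode = "precedence") {
  structure(list(input_dir = input_dir, quarters = quarters, target = target,
                 drug_file = drug_file, meddra_file = meddra_file,
                 out_dir = out_dir, thresholds = thresholds, priors = priors,
                 ebgm_z = ebgm_z, seed = as.integer(seed),
                 synthetic = synthetic, haldane = haldane, ps_only = ps_only,
                 dedup_within_case = dedup_within_case,
                 outcome_mode = outcome_mode),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Unknown keys are rejected so typos fail loudly; omitted keys take the
#' [run_config()] defaults. `thresholds`, `priors` and `synthetic` may be
#' given as nested maps of their respective arguments.
#'
#' @param path Path to a YAML configuration.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$thresholds)) {
    raw$thresholds <- do.call(signal_thresholds, raw$thresholds)
  }
  if (!is.null(raw$priors)) raw$priors <- do.call(bcpnn_priors, raw$priors)
  do.call(run_config, raw)
}

#' Generate a synthetic quarter from a run configuration
#'
#' Wraps [synthetic_config()] + [generate_faers()]: builds the generator
#' configuration from `config$synthetic` (seeded with `config$seed`) and
#' writes the quarter into `config$input_dir`.
#'
#' @param config A `run_config` with a non-`NULL` `synthetic` entry.
#' @return Invisibly, the ground truth from [generate_faers()].
#' @export
run_generate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  args <- config$synthetic
  if (is.null(args)) {
    stop("run_generate: config has no 'synthetic' section", call. = FALSE)
  }
  args$seed <- config$seed
  sc <- do.call(synthetic_config, args)
  generate_faers(sc, config$input_dir, quarter = config$quarters[1])
}

#' Run signal detection and write the report files
#'
#' @param config A `run_config`.
#' @return Invisibly, the `signal_run` (also written to `config$out_dir`).
#' @export
run_signals <- function(config) {
  stopifnot(inherits(config, "run_config"))
  run <- detect_signals(config$input_dir, config$quarters, config$target,
                        drug_file = config$drug_file,
                        meddra_file = config$meddra_file,
                        thresholds = config$thresholds,
                        priors = config$priors, ebgm_z = config$ebgm_z,
                        ps_only = config$ps_only,
                        dedup_within_case = config$dedup_within_case,
                        haldane = config$haldane)
  write_signal_tables(run, config$out_dir)
  invisible(run)
}

#' Run the golden-row harness and write its report
#'
#' @param config A `run_config`.
#' @param rows Printed rows (defaults to the bundled transcription).
#' @return Invisibly, the [check_goldens()] report (also written to
#'   `config$out_dir/goldens.tsv`).
#' @export
run_goldens <- function(config, rows = read_printed_rows()) {
  stopifnot(inherits(config, "run_config"))
  rep <- check_goldens(rows, ebgm_z = config$ebgm_z)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(rep, file.path(config$out_dir, "goldens.tsv"),
                     sep = "\t")
  invisible(rep)
}
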