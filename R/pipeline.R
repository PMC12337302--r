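## End-to-end pipeline orchestration with YAML configuration.

default_config <- function() {
  list(
    seed = 1L,
    outdir = "goldenpool_run",
    avoid_patterns = c("GGTCTC", "CGTCTC", "GAAGAC"),
    unique_kmer_k = 12L,
    hairpin_stem_min = 20L,
    hairpin_window = 250L,
    gc_min = 0,
    gc_window = 60L,
    gc_boost = 4,
    codon_table = "flat",
    codon_mode = "match_usage",
    reoptimize_codons = FALSE,
    deintronize = FALSE,
    max_payload = 198L,
    radius = 30L,
    oligo_budget = 250L,
    enzyme = "BbsI",
    hingeset_size = 20L,
    hingeset_path = NULL,
    matrix_path = NULL,
    matrix_mismatch_rate = 0.02,
    two_step_threshold = 2000L,
    target_block_length = 1050L,
    n_index_primers = NULL
  )
}

#' Build and validate a run configuration
#'
#' Starts from package defaults, overlaid with a YAML file and/or named
#' overrides. Unknown keys are rejected.
#'
#' @param path Optional YAML file of settings.
#' @param ... Named overrides.
#' @return A `run_config` list.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- default_config()
  user <- list()
  if (!is.null(path)) user <- yaml::read_yaml(path)
  dots <- list(...)
  user[names(dots)] <- dots
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg[names(user)] <- user
  structure(cfg, class = "run_config")
}

config_codon_table <- function(cfg) {
  if (inherits(cfg$codon_table, "codon_table")) return(cfg$codon_table)
  switch(cfg$codon_table,
         flat = flat_codon_table(),
         wobble = wobble_codon_table(),
         read_codon_table(cfg$codon_table))
}

config_constraints <- function(cfg) {
  design_constraints(avoid_patterns = cfg$avoid_patterns,
                     unique_kmer_k = cfg$unique_kmer_k,
                     hairpin_stem_min = cfg$hairpin_stem_min,
                     hairpin_window = cfg$hairpin_window,
                     gc_min = if (cfg$gc_min > 0) cfg$gc_min else NULL,
                     gc_window = cfg$gc_window,
                     gc_boost = cfg$gc_boost)
}

#' Run the design pipeline end to end
#'
#' For each target: domesticate (optionally re-optimize codon usage,
#' GC-tune, deintronize), fragment at hingeset junctions (targets longer
#' than `two_step_threshold` are routed to [plan_two_step()]), lay out
#' oligos and emit a pool table plus a machine-readable manifest. Failures
#' are isolated per target.
#'
#' @param targets Named character vector of CDSs, or a FASTA path.
#' @param config A [run_config()].
#' @param matrix Optional `overhang_matrix` (default: the synthetic
#'   matrix, or `config$matrix_path` when set).
#' @param hingeset Optional `hingeset` (default: optimized at
#'   `config$hingeset_size`, or read from `config$hingeset_path`).
#' @return The run manifest (list), invisibly written as JSON under
#'   `config$outdir` together with the resolved configuration.
#' @export
run_pipeline <- function(targets, config = run_config(), matrix = NULL,
                         hingeset = NULL) {
  if (is.character(targets) && length(targets) == 1L &&
      file.exists(targets)) {
    targets <- read_fasta(targets)
  }
  if (is.null(names(targets))) {
    names(targets) <- sprintf("target%02d", seq_along(targets))
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- config_codon_table(config)
  cons <- config_constraints(config)
  if (is.null(matrix)) {
    matrix <- if (!is.null(config$matrix_path)) {
      symmetrize_matrix(load_ligation_matrix(config$matrix_path))
    } else {
      synthetic_ligation_matrix(mismatch_rate = config$matrix_mismatch_rate,
                                seed = derive_seed(config$seed, 2L))
    }
  }
  if (!is_symmetrized(matrix)) matrix <- symmetrize_matrix(matrix)
  if (is.null(hingeset)) {
    hingeset <- if (!is.null(config$hingeset_path)) {
      read_hingesets(config$hingeset_path)[[1]]
    } else {
      optimize_hingeset(config$hingeset_size, matrix,
                        ga_config(seed = derive_seed(config$seed, 3L)))
    }
  }

  manifest <- list(config = unclass(config),
                   hingeset = list(members = hingeset$set$members,
                                   fidelity = hingeset$fidelity),
                   targets = list())
  plans <- list()
  for (nm in names(targets)) {
    entry <- tryCatch({
      res <- design_one_target(nm, toupper(targets[[nm]]), config, cons,
                               tab, matrix, hingeset)
      plans[[nm]] <- res$plan
      res$entry
    }, error = function(e) {
      list(target_id = nm, status = "error", message = conditionMessage(e))
    })
    manifest$targets[[nm]] <- entry
  }
  ok <- vapply(manifest$targets, function(x) x$status == "ok", logical(1))
  if (any(ok) && length(plans)) {
    one_step <- plans[vapply(plans, inherits, logical(1), "fragment_plan")]
    if (length(one_step)) {
      idx <- generate_primer_candidates(2L * length(one_step),
                                        seed = derive_seed(config$seed, 4L))
      pool <- build_pool_table(unname(one_step), idx$sequence,
                               enzyme = config$enzyme)
      write_pool_table(pool, file.path(config$outdir, "pool"))
      manifest$pool <- list(n_oligos = nrow(pool),
                            n_targets = length(one_step))
    }
  }
  manifest$status <- if (all(ok)) "ok" else "partial_failure"
  yaml::write_yaml(unclass(config),
                   file.path(config$outdir, "resolved_config.yaml"))
  jsonlite::write_json(manifest,
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

design_one_target <- function(nm, cds, config, cons, tab, matrix, hingeset) {
  seed <- derive_seed(config$seed, 5L)
  seq <- cds
  if (isTRUE(config$reoptimize_codons)) {
    seq <- codon_optimize(seq, tab, config$codon_mode, seed)
  }
  seq <- if (config$gc_min > 0) {
    as.character(gc_tune(seq, config$gc_min, cons, tab, seed))
  } else {
    as.character(domesticate(seq, cons, tab, seed))
  }
  residual_splice <- NA_integer_
  if (isTRUE(config$deintronize)) {
    di <- deintronize(seq, cons, tab, seed = seed)
    seq <- di$seq
    residual_splice <- nrow(di$residual)
  }
  metrics <- sequence_metrics(seq, tab, cons$gc_window)

  if (nchar(seq) > config$two_step_threshold) {
    plan <- plan_two_step(seq, hingeset, matrix,
                          target_block_length = config$target_block_length,
                          oligo_budget = config$oligo_budget,
                          radius = config$radius, target_id = nm)
    entry <- list(target_id = nm, status = "ok", mode = "two_step",
                  n_blocks = nrow(plan$blocks),
                  oligos_per_block = vapply(plan$per_block_fragment_plans,
                                            function(p) length(p$fragments),
                                            1L),
                  block_fidelity = plan$predicted_block_fidelity)
  } else {
    plan <- fragment_sequence(prepare_cds_part(seq), hingeset, matrix,
                              max_payload = config$oligo_budget - 52L,
                              radius = config$radius, target_id = nm)
    entry <- list(target_id = nm, status = "ok", mode = "one_step",
                  n_fragments = length(plan$fragments),
                  predicted_fidelity = plan$predicted_fidelity)
  }
  entry$gc <- metrics$gc
  entry$cai <- metrics$cai
  entry$residual_splice_sites <- residual_splice
  entry$length_nt <- nchar(seq)
  list(entry = entry, plan = plan)
}
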