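#' Pipeline configuration
#'
#' Bundles input paths, filter thresholds, the study design, and the
#' analysis flags for one end-to-end run. Referenced files are checked
#' at construction so misconfiguration fails before any computation.
#'
#' @param observations Path to the observation TSV.
#' @param precursors Path to the precursor FASTA.
#' @param out_dir Output directory (created if needed).
#' @param filters A [filter_config()].
#' @param design A [study_design()].
#' @param use_fdr Apply the target-decoy FDR gate (for inputs carrying
#'   decoy labels; engine exports already filtered upstream leave this
#'   off).
#' @param paired Paired condition-contrast t-tests.
#' @param p_adjust P-value adjustment method for the quant table
#'   (`"none"` reports raw p-values, as the presence rule's companion
#'   testing did; `"BH"` enables Benjamini-Hochberg).
#' @param dialect Optional column-name mapping for foreign observation
#'   exports (see [read_observations()]).
#' @param seed Integer seed recorded in the manifest (the pipeline
#'   itself is deterministic; the seed matters when the input was
#'   generated in the same session).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(observations, precursors, out_dir,
                            filters = filter_config(),
                            design = study_design(),
                            use_fdr = FALSE, paired = FALSE,
                            p_adjust = "none", dialect = NULL, seed = 1L) {
  if (!file.exists(observations)) {
    abort(sprintf("observations file not found: %s", observations))
  }
  if (!file.exists(precursors)) {
    abort(sprintf("precursor FASTA not found: %s", precursors))
  }
  structure(
    list(
      observations = observations, precursors = precursors,
      out_dir = out_dir, filters = filters, design = design,
      use_fdr = use_fdr, paired = paired, p_adjust = p_adjust,
      dialect = dialect, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full secretion-signature pipeline
#'
#' Read and validate -> filter -> map -> call presence -> signatures ->
#' quantitation, writing every result table plus a run log and a
#' manifest (input hashes, config snapshot, output hashes, package
#' version) under `config$out_dir`. Deterministic given the inputs. Any
#' stage failure removes partial outputs and rethrows with the stage
#' named.
#'
#' Outputs: `presence_matrix.tsv` (wide +/- table),
#' `subject_detail_<condition>.tsv`, `signature_report.json`,
#' `venn_<condition>.tsv`, `precursor_tally_<condition>.tsv`,
#' `peptide_labels_<condition>.tsv`, `quant_cells.tsv`,
#' `quant_contrasts.tsv`, `mapping.tsv`, `filter_report.tsv`,
#' `row_errors.tsv`, `run_log.txt`, `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`matrix`,
#'   `report`, `quant`, `mapping`, `filter_report`) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out)) abort(sprintf("cannot create output directory: %s", out))
  written <- character()
  log_lines <- character()
  # log lines carry no timestamps so reruns are byte-identical
  log <- function(...) {
    line <- sprintf("[neuropepsig] %s", sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  emit <- function(x, name) {
    path <- file.path(out, name)
    readr::write_tsv(x, path, progress = FALSE)
    written <<- c(written, path)
    path
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
    })
  }

  obs <- run_stage("read", {
    o <- read_observations(config$observations,
      dialect = config$dialect, design = config$design
    )
    errs <- attr(o, "errors")
    log("read %d observations (%d row errors)", nrow(o), nrow(errs))
    emit(errs, "row_errors.tsv")
    o
  })
  precursors <- run_stage("read", read_precursors(config$precursors))
  log("read %d precursors", nrow(precursors))

  obs_f <- run_stage("filter", {
    o <- apply_filters(obs, config$filters, use_fdr = config$use_fdr)
    rep <- attr(o, "filter_report")
    emit(rep, "filter_report.tsv")
    for (i in seq_len(nrow(rep))) {
      log(
        "filter %s: %d -> %d rows", rep$stage[i], rep$n_in[i], rep$n_out[i]
      )
    }
    o
  })

  mapping <- run_stage("map", {
    m <- map_peptides(obs_f, precursors)
    unm <- attr(m, "unmapped")
    log("mapped %d distinct peptides (%d unmappable)", nrow(m), length(unm))
    emit(
      dplyr::select(m, -"all_sites") |>
        dplyr::mutate(n_sites = as.integer(.data$n_sites)),
      "mapping.tsv"
    )
    m
  })

  matrix <- run_stage("presence", {
    mat <- build_presence_matrix(obs_f, mapping, config$design)
    log("presence matrix: %d peptides", nrow(mat$peptides))
    emit(presence_wide(mat), "presence_matrix.tsv")
    for (cond in config$design$conditions) {
      emit(
        subject_detail_wide(mat, cond),
        sprintf("subject_detail_%s.tsv", cond)
      )
    }
    mat
  })

  report <- run_stage("signatures", {
    rep <- signature_report(matrix)
    for (cond in names(rep$conditions)) {
      cc <- rep$conditions[[cond]]
      log(
        "%s: union %d, venn %s", cond, cc$union,
        paste(sprintf("%s=%d", names(cc$venn$counts), cc$venn$counts),
          collapse = " "
        )
      )
      emit(
        tibble::tibble(
          class = names(cc$venn$counts), count = as.integer(cc$venn$counts)
        ),
        sprintf("venn_%s.tsv", cond)
      )
      emit(cc$precursor_tally, sprintf("precursor_tally_%s.tsv", cond))
      emit(cc$labels, sprintf("peptide_labels_%s.tsv", cond))
    }
    path <- file.path(out, "signature_report.json")
    write_signature_report(rep, path)
    written <- c(written, path)
    rep
  })

  quant <- run_stage("quant", {
    q <- quantify_peptides(obs_f, matrix,
      paired = config$paired, p_adjust = config$p_adjust
    )
    log(
      "quant: %d cells, %d contrasts (%d significant)",
      nrow(q$cells), nrow(q$contrasts), sum(q$contrasts$significant)
    )
    emit(q$cells, "quant_cells.tsv")
    emit(q$contrasts, "quant_contrasts.tsv")
    q
  })

  log_path <- file.path(out, "run_log.txt")
  writeLines(log_lines, log_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("neuropepsig")),
    seed = config$seed,
    inputs = as.list(tools::md5sum(c(config$observations, config$precursors))),
    config = list(
      filters = unclass(config$filters),
      use_fdr = config$use_fdr, paired = config$paired,
      p_adjust = config$p_adjust,
      design = list(
        groups = config$design$groups,
        n_culture_reps = config$design$n_culture_reps,
        n_tech_reps = config$design$n_tech_reps,
        conditions = config$design$conditions,
        group_presence_threshold = as.list(config$design$group_presence_threshold),
        tech_threshold = config$design$tech_threshold,
        culture_threshold = config$design$culture_threshold
      )
    ),
    outputs = as.list(tools::md5sum(sort(c(written, log_path))))
  )
  jsonlite::write_json(
    manifest, file.path(out, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(
    matrix = matrix, report = report, quant = quant, mapping = mapping,
    filter_report = attr(obs_f, "filter_report"), out_dir = out
  ))
}
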