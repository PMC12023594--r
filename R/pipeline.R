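# End-to-end driver and results export.

#' Run the full reduced-graph series analysis
#'
#' Cleans the dataset, builds reduced graphs, extracts RG cores, assigns
#' every molecule to every core it contains (resolving ambiguous mappings),
#' and computes the SAR annotations.
#'
#' @param records A tibble with columns `compound_id`, `smiles`, `pic50`
#'   (e.g. from [read_dataset()]), or a file path accepted by it.
#' @param config An [rg_config()].
#' @return An object of class `rg_result`: list(records, rgs, cores,
#'   assignments, annotations, core_tables, overlap, summary, config).
#' @examples
#' \dontrun{
#' res <- rg_run(make_series_demo()$records, rg_config(min_core_size = 4))
#' res$summary
#' }
#' @export
rg_run <- function(records, config = rg_config()) {
  if (is.character(records) && length(records) == 1) {
    records <- read_dataset(records)
  }
  records <- clean_dataset(records, config)
  if (nrow(records) == 0) stop("no records survived cleaning", call. = FALSE)
  rgs <- build_rgs(records, config)
  cores <- extract_cores(rgs, config)
  assignments <- assign_all(rgs, cores)
  annotations <- lapply(cores, annotate_core, assignments = assignments, rgs = rgs)
  core_tables <- lapply(cores, build_core_table, assignments = assignments, rgs = rgs)
  structure(list(
    records = records,
    rgs = rgs,
    cores = cores,
    assignments = assignments,
    annotations = annotations,
    core_tables = core_tables,
    overlap = overlap_matrix(assignments),
    summary = dataset_summary(records, rgs),
    config = config
  ), class = "rg_result")
}

#' @export
print.rg_result <- function(x, ...) {
  cat("<rg_result> ", nrow(x$records), " molecules, ",
      x$summary$n_unique_rgs, " unique RGs, ", length(x$cores), " cores\n",
      sep = "")
  for (core in x$cores) print(core)
  invisible(x)
}

#' Export analysis results to a directory
#'
#' Writes, under `path`: one JSON document per core (core SMARTS, per-node
#' substructure tables with activity statistics and pie-segment fractions),
#' one CSV per core with the combined-substructure rows, a core-overlap
#' matrix CSV, a dataset summary CSV, and a per-molecule assignment CSV.
#'
#' @param result An `rg_result` from [rg_run()].
#' @param path Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
export_results <- function(result, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path, call. = FALSE)
  written <- character(0)

  f <- file.path(path, "summary.csv")
  utils::write.csv(result$summary, f, row.names = FALSE)
  written <- c(written, f)

  if (length(result$cores) > 0) {
    f <- file.path(path, "overlap.csv")
    utils::write.csv(as.data.frame(result$overlap), f, row.names = TRUE)
    written <- c(written, f)

    assign_rows <- list()
    for (k in seq_along(result$cores)) {
      core <- result$cores[[k]]
      ann <- result$annotations[[k]]
      pies <- pie_metadata(core, ann)
      doc <- list(
        core_id = core$core_id,
        core_smarts = core$core_smarts,
        sub_minimal = core$sub_minimal,
        member_count = length(result$assignments[[k]]$member_ids),
        nodes = lapply(pies, function(p) {
          seg <- ann[ann$node_index == p$node_index, ]
          list(
            node_index = p$node_index,
            label = p$label,
            size = p$size,
            substructures = lapply(seq_len(nrow(seg)), function(r) {
              list(smarts = seg$substructure_smarts[r],
                   count = seg$count[r],
                   pic50_median = seg$pic50_median[r],
                   pic50_mean = seg$pic50_mean[r],
                   pic50_std = seg$pic50_std[r])
            }),
            segments = p$segments$fraction
          )
        })
      )
      f <- file.path(path, sprintf("core_%03d.json", core$core_id))
      jsonlite::write_json(doc, f, auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null", pretty = TRUE)
      written <- c(written, f)

      f <- file.path(path, sprintf("core_%03d_table.csv", core$core_id))
      utils::write.csv(result$core_tables[[k]], f, row.names = FALSE)
      written <- c(written, f)

      a <- result$assignments[[k]]
      for (id in a$member_ids) {
        mp <- a$mappings[[id]]
        assign_rows[[length(assign_rows) + 1]] <- data.frame(
          compound_id = id,
          core_id = core$core_id,
          ambiguous = mp$ambiguous,
          resolution_stage = mp$stage,
          node_substructures = paste(result$rgs[[id]]$substructure[mp$mapping],
                                     collapse = "|"),
          stringsAsFactors = FALSE
        )
      }
    }
    f <- file.path(path, "assignments.csv")
    utils::write.csv(do.call(rbind, assign_rows), f, row.names = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}
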