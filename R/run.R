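#' Run the full unlink pipeline on a directory
#'
#' Wires the whole workflow: optional archive extraction, scan, grouping
#' by series, remap planning, and rewriting — the programmatic equivalent
#' of the command-line `unlink run`.  With `dry_run` the plan is built
#' and summarised but no byte on disk changes.
#'
#' @param input directory of DICOM files (or zip archives, with
#'   `unzip = TRUE`).
#' @param options a [remap_options()] object.
#' @param modalities optional modality filter tokens (see
#'   [scan_directory()]).
#' @param unzip extract `.zip` archives under `input` before scanning.
#' @param unzip_delete remove archives after successful extraction.
#' @param output_dir write modified copies here instead of overwriting in
#'   place.
#' @param dry_run plan and summarise only; never writes.
#' @param uid_root optional registered UID root for replacement UIDs
#'   (defaults to the `2.25.` UUID-derived scheme).
#' @param seed optional integer making generated UIDs reproducible.
#' @param report_path optional path for a JSON change report.
#' @param progress_sink optional `function(i, n, path)` per-file callback;
#'   `NULL` for silence.
#' @return An `unlink_run` object: `status` (0 = success, 1 = some files
#'   failed, 2 = nothing in scope), `records`, `groups`, `plan`,
#'   `report` (`NULL` for dry runs), `extraction`.
#' @examples
#' \dontrun{
#' run <- unlink_run("exports/", remap_options(
#'   change_frame_of_reference = TRUE, fourdct_mode = TRUE),
#'   modalities = "CT")
#' run$status
#' }
#' @export
unlink_run <- function(input, options = remap_options(), modalities = NULL,
                       unzip = FALSE, unzip_delete = FALSE,
                       output_dir = NULL, dry_run = FALSE,
                       uid_root = NULL, seed = NULL, report_path = NULL,
                       progress_sink = NULL) {
  extraction <- NULL
  if (unzip) {
    extraction <- extract_archives(input, delete_after = unzip_delete)
  }

  records <- scan_directory(input, modalities = modalities)
  groups <- group_by_series(records)
  if (!length(groups)) {
    message("no DICOM files in scope under '", input, "'")
    return(structure(list(status = 2L, records = records, groups = groups,
                          plan = NULL, report = NULL,
                          extraction = extraction),
                     class = "unlink_run"))
  }

  plan <- build_plan(groups, options,
                     uid_source = uid_generator(root = uid_root,
                                                seed = seed))
  if (dry_run) {
    message(paste(plan_summary(plan), collapse = "\n"))
    message("dry run: no files written")
    return(structure(list(status = 0L, records = records, groups = groups,
                          plan = plan, report = NULL,
                          extraction = extraction),
                     class = "unlink_run"))
  }

  report <- apply_plan(plan, records, output_dir = output_dir,
                       progress_sink = progress_sink)
  if (!is.null(report_path)) write_change_report(report, report_path)
  totals <- attr(report, "totals")
  structure(list(status = if (totals$files_failed > 0L) 1L else 0L,
                 records = records, groups = groups, plan = plan,
                 report = report, extraction = extraction),
            class = "unlink_run")
}

#' @export
print.unlink_run <- function(x, ...) {
  cat("<unlink_run> status ", x$status, "\n", sep = "")
  if (!is.null(x$plan)) cat(plan_summary(x$plan), sep = "\n")
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
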