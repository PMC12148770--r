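# Step two of the pipeline: apply a remap plan to files on disk.
#
# Rewriting is byte splicing, not re-encoding: the element index from the
# parser locates the targeted top-level elements, replacement elements are
# encoded in the source transfer syntax, and every other byte range is
# copied verbatim.  The file-meta group length (0002,0000) is re-derived
# when the Media Storage SOP Instance UID changes size.

META_START <- 133L  # first file-meta element (after 128-byte preamble + DICM)

rewrite_file_bytes <- function(bytes, new_values) {
  p <- parse_dicom_bytes(bytes)
  changed <- character(0)

  top <- p$dataset[p$dataset$depth == 0L, , drop = FALSE]
  data_chunks <- lapply(seq_len(nrow(top)), function(i) {
    row <- top[i, ]
    tag <- tag_str(row$group, row$element)
    if (!is.null(new_values[[tag]])) {
      changed <<- c(changed, tag)
      encode_element(row$group, row$element, "UI", new_values[[tag]],
                     explicit = p$explicit)
    } else {
      bytes[row$offset:(row$end_offset - 1L)]
    }
  })

  meta <- p$meta[p$meta$depth == 0L, , drop = FALSE]
  new_sop <- new_values[[TAG_SOP_INSTANCE_UID]]
  meta_chunks <- lapply(seq_len(nrow(meta)), function(i) {
    row <- meta[i, ]
    if (!is.null(new_sop) && row$group == 2L && row$element == 3L) {
      changed <<- c(changed, TAG_MEDIA_STORAGE_SOP)
      encode_element(2L, 3L, "UI", new_sop, explicit = TRUE)
    } else {
      bytes[row$offset:(row$end_offset - 1L)]
    }
  })
  meta_bytes <- do.call(c, meta_chunks)

  # re-derive (0002,0000): its value is the byte count of the meta group
  # after its own element, which shifts when the new SOP UID differs in
  # length from the old one
  gl <- which(meta$group == 2L & meta$element == 0L)
  if (length(gl) == 1L && TAG_MEDIA_STORAGE_SOP %in% changed) {
    gl_value_at <- meta$value_offset[gl] - META_START + 1L  # rel, 1-based
    gl_end_rel <- meta$end_offset[gl] - META_START          # bytes before rest
    meta_bytes[gl_value_at:(gl_value_at + 3L)] <-
      u32_le(length(meta_bytes) - gl_end_rel)
  }

  list(bytes = c(bytes[1:132], meta_bytes, do.call(c, data_chunks)),
       tags_changed = changed)
}

#' Apply a remap plan to scanned files
#'
#' Rewrites exactly the planned UID tags of every in-scope file —
#' Frame of Reference (0020,0052), Series Instance UID (0020,000E), SOP
#' Instance UID (0008,0018) plus its file-meta mirror (0002,0003) — and
#' nothing else: all other attributes, pixel data and the transfer syntax
#' are byte-preserved.  By default files are overwritten in place (the
#' original tool's behaviour); pass `output_dir` to write modified copies
#' instead, preserving the directory layout below the scan root.
#'
#' A file that cannot be written is recorded in the report and processing
#' continues; writes themselves are atomic ([atomic_write()]), so a
#' failure never leaves a truncated file.
#'
#' @param plan a `remap_plan` from [build_plan()], built from these
#'   records.
#' @param records data frame from [scan_directory()]; only in-scope rows
#'   are touched.
#' @param output_dir optional destination directory; `NULL` rewrites in
#'   place.
#' @param progress_sink optional `function(i, n, path)` called once per
#'   file as it completes.
#' @param writer the low-level write function, `function(bytes, dest)`;
#'   replaceable for fault-injection testing.  Defaults to
#'   [atomic_write()].
#' @return A `change_report` data frame with one row per in-scope file:
#'   `path`, `dest`, `tags_changed` (list column), `old` / `new` UID
#'   values per tag (list columns), `write_ok`, `error`; totals in
#'   `attr(, "totals")`.
#' @export
apply_plan <- function(plan, records, output_dir = NULL,
                       progress_sink = NULL, writer = atomic_write) {
  stopifnot(inherits(plan, "remap_plan"))
  root <- attr(records, "root") %||% "."
  recs <- records[records$parse_ok & is.na(records$skip_reason), ,
                  drop = FALSE]
  recs <- recs[order(recs$path), , drop = FALSE]
  n <- nrow(recs)
  o <- plan$options

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- recs[i, ]
    dest <- if (is.null(output_dir)) rec$path
            else file.path(output_dir, rel_path(rec$path, root))
    res <- tryCatch({
      new_values <- plan_targets_for(plan, rec)
      bytes <- readBin(rec$path, "raw", n = file.size(rec$path))
      if (length(new_values)) {
        rw <- rewrite_file_bytes(bytes, new_values)
        writer(rw$bytes, ensure_parent(dest))
        tags <- rw$tags_changed
      } else {
        # nothing targeted: untouched in place, byte-identical copy
        # when an output directory was requested
        if (!is.null(output_dir)) writer(bytes, ensure_parent(dest))
        tags <- character(0)
        new_values <- list()
      }
      list(tags = tags, new_values = new_values, err = NA_character_)
    }, error = function(e) {
      list(tags = character(0), new_values = list(),
           err = conditionMessage(e))
    })

    old_vals <- c("(0020,0052)" = rec$frame_of_reference_uid,
                  "(0020,000E)" = rec$series_uid,
                  "(0008,0018)" = rec$sop_uid,
                  "(0002,0003)" = rec$sop_uid)
    tags <- res$tags
    rows[[i]] <- data.frame(
      path = rec$path, dest = dest,
      tags_changed = I(list(sort(tags))),
      old = I(list(unname(old_vals[tags]))),
      new = I(list(vapply(tags, function(t) {
        if (t == TAG_MEDIA_STORAGE_SOP) t <- TAG_SOP_INSTANCE_UID
        res$new_values[[t]] %||% NA_character_
      }, character(1), USE.NAMES = FALSE))),
      write_ok = is.na(res$err), error = res$err,
      stringsAsFactors = FALSE)
    if (!is.null(progress_sink)) progress_sink(i, n, rec$path)
  }

  report <- if (n) do.call(rbind, rows) else
    data.frame(path = character(), dest = character(),
               tags_changed = I(list()), old = I(list()), new = I(list()),
               write_ok = logical(), error = character(),
               stringsAsFactors = FALSE)
  rownames(report) <- NULL
  attr(report, "totals") <- list(files_changed = sum(report$write_ok),
                                 files_failed = sum(!report$write_ok))
  class(report) <- c("change_report", class(report))
  report
}

# the planned replacement values for one file; a file the plan does not
# cover is a pipeline error and is reported per-file, not fatal
plan_targets_for <- function(plan, rec) {
  o <- plan$options
  out <- list()
  if (o$change_sop_uid) {
    v <- plan$sop_map[rec$sop_uid]
    if (is.na(v)) stop("file not covered by plan (SOP UID ", rec$sop_uid,
                       ")", call. = FALSE)
    out[[TAG_SOP_INSTANCE_UID]] <- unname(v)
  }
  if (o$change_series_uid) {
    v <- plan$series_map[rec$series_uid]
    if (is.na(v)) stop("file not covered by plan (series UID ",
                       rec$series_uid, ")", call. = FALSE)
    out[[TAG_SERIES_UID]] <- unname(v)
  }
  if (o$change_frame_of_reference && !is.na(rec$frame_of_reference_uid)) {
    v <- plan$for_by_series[rec$series_uid]
    if (is.na(v)) stop("file not covered by plan (series UID ",
                       rec$series_uid, " has no planned frame of reference)",
                       call. = FALSE)
    out[[TAG_FRAME_OF_REFERENCE]] <- unname(v)
  }
  out
}

ensure_parent <- function(dest) {
  d <- dirname(dest)
  if (!dir.exists(d)) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  dest
}

#' @export
print.change_report <- function(x, ...) {
  t <- attr(x, "totals")
  cat("<change_report> ", nrow(x), " file(s): ", t$files_changed,
      " written, ", t$files_failed, " failed\n", sep = "")
  if (t$files_failed > 0) {
    bad <- x[!x$write_ok, ]
    for (i in seq_len(nrow(bad))) {
      cat("  FAILED ", bad$path[i], ": ", bad$error[i], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Serialise a change report to JSON
#'
#' @param report a `change_report` from [apply_plan()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_change_report <- function(report, path) {
  t <- attr(report, "totals")
  entries <- lapply(seq_len(nrow(report)), function(i) {
    list(path = report$path[i], dest = report$dest[i],
         tags_changed = report$tags_changed[[i]],
         old = report$old[[i]], new = report$new[[i]],
         write_ok = report$write_ok[i],
         error = if (is.na(report$error[i])) NULL else report$error[i])
  })
  jsonlite::write_json(list(files = entries, totals = t), path,
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}
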