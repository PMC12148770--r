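# Automated verification that only the desired attributes changed.
#
# Snapshots record a digest of every element's value bytes (pixel data
# included, as a digest rather than a copy), keyed by tag path so that
# sequence items compare recursively.  Group-length elements (gggg,0000)
# are excluded: they are encoding bookkeeping, and the file-meta group
# length legitimately shifts whenever a replacement UID differs in byte
# length from the original.

#' Snapshot every DICOM file under a directory
#'
#' @param root directory to snapshot.
#' @param recurse descend into subdirectories.
#' @return A `dicom_snapshot`: named list (relative path -> element
#'   inventory data frame with `path` (tag path), `vr`, `value_len`,
#'   `digest`, `value` (text for short string VRs, else `NA`)), with
#'   unreadable files listed in `attr(, "unreadable")`.
#' @export
dicom_snapshot <- function(root, recurse = TRUE) {
  if (!dir.exists(root)) {
    stop("snapshot root '", root, "' does not exist", call. = FALSE)
  }
  files <- sort(list.files(root, recursive = recurse, full.names = TRUE))
  files <- files[!dir.exists(files) & vapply(files, has_dicom_magic,
                                             logical(1))]
  unreadable <- character(0)
  inv <- list()
  for (f in files) {
    snap <- tryCatch(snapshot_one(f), error = function(e) e)
    if (inherits(snap, "error")) {
      warning("cannot snapshot '", f, "': ", conditionMessage(snap),
              call. = FALSE)
      unreadable <- c(unreadable, f)
    } else {
      inv[[rel_path(f, root)]] <- snap
    }
  }
  structure(inv, root = root, unreadable = unreadable,
            class = "dicom_snapshot")
}

snapshot_one <- function(path) {
  dcm <- read_dicom(path)
  idx <- rbind(dcm$meta, dcm$dataset)
  # drop group lengths and sequence containers (children carry content)
  idx <- idx[!is_group_length(idx$element) & idx$vr != "SQ", , drop = FALSE]
  vals <- lapply(seq_len(nrow(idx)), function(i) {
    element_raw(dcm$bytes, idx[i, ])
  })
  data.frame(
    path = idx$path, vr = idx$vr, value_len = idx$value_len,
    digest = vapply(vals, rlang::hash, character(1)),
    value = vapply(seq_len(nrow(idx)), function(i) {
      if (idx$vr[i] %in% STRING_VRS && idx$value_len[i] <= 128) {
        element_text(dcm$bytes, idx[i, ])
      } else NA_character_
    }, character(1)),
    stringsAsFactors = FALSE)
}

#' Diff two snapshots at tag level
#'
#' Pairs files by relative path (both in-place and `output_dir` runs
#' preserve names) and lists exactly the tags whose value bytes differ.
#'
#' @param before,after `dicom_snapshot` objects over the same logical
#'   files.
#' @return An `attribute_diff` data frame: `file`, `tag`, `old`, `new`
#'   (text value or `<len bytes #digest>` for binary elements), with
#'   `files_compared`, `added` and `removed` in attributes.  Zero rows
#'   means the trees are attribute-identical.
#' @export
diff_datasets <- function(before, after) {
  stopifnot(inherits(before, "dicom_snapshot"),
            inherits(after, "dicom_snapshot"))
  common <- intersect(names(before), names(after))
  rows <- list()
  for (f in common) {
    b <- before[[f]]
    a <- after[[f]]
    m <- merge(b, a, by = "path", all = TRUE, suffixes = c(".old", ".new"))
    diff <- m[is.na(m$digest.old) | is.na(m$digest.new) |
                m$digest.old != m$digest.new, , drop = FALSE]
    if (nrow(diff)) {
      rows[[f]] <- data.frame(
        file = f, tag = diff$path,
        old = render_value(diff$value.old, diff$value_len.old,
                           diff$digest.old),
        new = render_value(diff$value.new, diff$value_len.new,
                           diff$digest.new),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(), tag = character(), old = character(),
               new = character(), stringsAsFactors = FALSE)
  out <- out[order(out$file, out$tag), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "files_compared") <- length(common)
  attr(out, "added") <- setdiff(names(after), names(before))
  attr(out, "removed") <- setdiff(names(before), names(after))
  class(out) <- c("attribute_diff", class(out))
  out
}

render_value <- function(value, len, digest) {
  ifelse(is.na(digest), "<absent>",
         ifelse(!is.na(value), value,
                sprintf("<%d bytes %s>", as.integer(len),
                        substr(digest, 1, 8))))
}

#' Assert that a diff touches only allowed tags
#'
#' The headline safety check: after a run, the per-file diff must contain
#' nothing beyond the attributes the user asked to change.
#'
#' @param diff an `attribute_diff` from [diff_datasets()].
#' @param allowed character vector of permitted tag strings, e.g.
#'   `c("(0008,0018)", "(0002,0003)")`.
#' @return `TRUE` if every differing tag of every file is allowed and no
#'   files appeared or disappeared; otherwise `FALSE` with the offending
#'   rows in `attr(, "violations")`.
#' @export
assert_only_changed <- function(diff, allowed) {
  stopifnot(inherits(diff, "attribute_diff"))
  bad <- diff[!diff$tag %in% allowed, , drop = FALSE]
  ok <- nrow(bad) == 0L && length(attr(diff, "added")) == 0L &&
    length(attr(diff, "removed")) == 0L
  structure(ok, violations = bad,
            added = attr(diff, "added"), removed = attr(diff, "removed"))
}

#' @export
print.attribute_diff <- function(x, ...) {
  cat("<attribute_diff> ", attr(x, "files_compared"),
      " file(s) compared; ", nrow(x), " differing tag(s)\n", sep = "")
  if (length(attr(x, "added"))) {
    cat("  added files:", paste(attr(x, "added"), collapse = ", "), "\n")
  }
  if (length(attr(x, "removed"))) {
    cat("  removed files:", paste(attr(x, "removed"), collapse = ", "), "\n")
  }
  if (nrow(x)) {
    print.data.frame(utils::head(as.data.frame(x), 20))
    if (nrow(x) > 20) cat("  ... and", nrow(x) - 20, "more rows\n")
  }
  invisible(x)
}

#' Serialise an attribute diff to JSON
#'
#' @param diff an `attribute_diff`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_diff_json <- function(diff, path) {
  jsonlite::write_json(
    list(files_compared = attr(diff, "files_compared"),
         added = attr(diff, "added"), removed = attr(diff, "removed"),
         differences = as.data.frame(diff)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
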