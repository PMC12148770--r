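# DICOM Part-10 reader.
#
# The tool's safety contract is byte preservation of every element it does
# not target, so files are handled as raw bytes plus an *index* of element
# positions; values are fetched on demand and rewriting splices bytes
# rather than re-encoding the whole dataset.  Explicit and Implicit VR
# Little Endian are supported (the syntaxes CT/MR/PET exports use);
# sequences and undefined lengths are indexed recursively so the verify
# differ can address nested elements by path.

UNDEFINED_LEN <- 4294967295

#' Read and index a DICOM Part-10 file
#'
#' Parses the file-meta group and main dataset into an element index
#' (tag, VR, byte offsets) without copying values.  Used by the scanner,
#' the rewriter and the verify differ.
#'
#' @param path path to a DICOM Part-10 file.
#' @return An object of class `dicom_file`: list with `path`, `bytes`
#'   (raw), `meta` and `dataset` (element index data frames),
#'   `transfer_syntax` and `explicit`.
#' @seealso [dcm_value()] to fetch a string value by tag.
#' @export
read_dicom <- function(path) {
  n <- file.size(path)
  if (is.na(n)) stop("cannot read '", path, "'", call. = FALSE)
  bytes <- readBin(path, "raw", n = n)
  dcm <- parse_dicom_bytes(bytes)
  dcm$path <- path
  dcm
}

parse_dicom_bytes <- function(bytes) {
  n <- length(bytes)
  if (n < 140L || rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM Part-10 file (no DICM magic)", call. = FALSE)
  }

  # file meta: always Explicit VR Little Endian, group 0002 only
  meta_rows <- list()
  at <- 133L
  while (at + 7L <= n && read_u16(bytes, at) == 2L) {
    row <- parse_one_element(bytes, at, n, explicit = TRUE, prefix = "",
                             depth = 0L)
    meta_rows[[length(meta_rows) + 1L]] <- row$rows
    at <- row$next_at
  }
  meta <- do.call(rbind, meta_rows)
  if (is.null(meta)) stop("missing DICOM file meta group", call. = FALSE)

  ts <- element_text(bytes, meta[meta$group == 2L & meta$element == 16L, ])
  if (!length(ts) || is.na(ts)) ts <- TS_EXPLICIT_LE
  explicit <- ts == TS_EXPLICIT_LE
  if (!ts %in% c(TS_EXPLICIT_LE, TS_IMPLICIT_LE)) {
    stop("unsupported transfer syntax '", ts, "'", call. = FALSE)
  }

  data_rows <- list()
  while (at + 7L <= n) {
    row <- parse_one_element(bytes, at, n, explicit = explicit, prefix = "",
                             depth = 0L)
    data_rows[[length(data_rows) + 1L]] <- row$rows
    at <- row$next_at
  }
  if (at != n + 1L) stop("trailing garbage after last element", call. = FALSE)
  dataset <- do.call(rbind, data_rows)

  structure(list(path = NA_character_, bytes = bytes, meta = meta,
                 dataset = dataset %||% empty_index(),
                 transfer_syntax = ts, explicit = explicit),
            class = "dicom_file")
}

empty_index <- function() {
  data.frame(path = character(), group = integer(), element = integer(),
             vr = character(), offset = integer(), value_offset = integer(),
             value_len = numeric(), end_offset = integer(), depth = integer(),
             stringsAsFactors = FALSE)
}

index_row <- function(path, group, element, vr, offset, value_offset,
                      value_len, end_offset, depth) {
  data.frame(path = path, group = group, element = element, vr = vr,
             offset = offset, value_offset = value_offset,
             value_len = value_len, end_offset = end_offset, depth = depth,
             stringsAsFactors = FALSE)
}

# parse the element starting at `at` (1-based); returns its index rows
# (the element itself plus any sequence children) and the next offset
parse_one_element <- function(bytes, at, end, explicit, prefix, depth) {
  if (at + 7L > end) stop("truncated element header", call. = FALSE)
  group <- read_u16(bytes, at)
  element <- read_u16(bytes, at + 2L)
  tag <- tag_str(group, element)
  path <- paste0(prefix, tag)

  if (explicit && group != 0xFFFE) {
    vr <- rawToChar(bytes[(at + 4L):(at + 5L)])
    if (vr %in% LONG_VRS) {
      len <- read_u32(bytes, at + 8L)
      value_at <- at + 12L
    } else {
      len <- read_u16(bytes, at + 6L)
      value_at <- at + 8L
    }
  } else {
    vr <- if (group == 0xFFFE) "" else dict_lookup_vr(group, element)
    len <- read_u32(bytes, at + 4L)
    value_at <- at + 8L
    if (vr %in% c("UN", "") && len == UNDEFINED_LEN) vr <- "SQ"
  }

  if (len == UNDEFINED_LEN) {
    if (!vr %in% c("SQ", "OB", "UN")) {
      stop("undefined length on VR ", vr, " at ", tag, call. = FALSE)
    }
    items <- parse_items(bytes, value_at, end, explicit, path, depth,
                         recurse = vr == "SQ")
    rows <- index_row(path, group, element, vr, at, value_at,
                      items$content_end - value_at, items$next_at, depth)
    if (!is.null(items$rows)) rows <- rbind(rows, items$rows)
    return(list(rows = rows, next_at = items$next_at))
  }

  value_end <- value_at + len - 1
  if (value_end > end) stop("element ", tag, " overruns file", call. = FALSE)
  rows <- index_row(path, group, element, vr, at, value_at, len,
                    as.integer(value_end + 1), depth)
  if (vr == "SQ" && len > 0) {
    items <- parse_items(bytes, value_at, as.integer(value_end), explicit,
                         path, depth, recurse = TRUE)
    if (!is.null(items$rows)) rows <- rbind(rows, items$rows)
  }
  list(rows = rows, next_at = as.integer(value_end + 1))
}

# sequence items: (FFFE,E000) ... terminated by end-of-span or (FFFE,E0DD)
parse_items <- function(bytes, at, end, explicit, prefix, depth, recurse) {
  rows <- list()
  i <- 0L
  repeat {
    if (at > end) {
      if (at == end + 1L) break  # defined-length SQ consumed exactly
      stop("sequence in ", prefix, " overruns its span", call. = FALSE)
    }
    group <- read_u16(bytes, at)
    element <- read_u16(bytes, at + 2L)
    len <- read_u32(bytes, at + 4L)
    if (group == 0xFFFE && element == 0xE0DD) {  # sequence delimitation
      return(list(rows = if (length(rows)) do.call(rbind, rows),
                  content_end = at, next_at = at + 8L))
    }
    if (!(group == 0xFFFE && element == 0xE000)) {
      stop("expected item tag in ", prefix, ", found ",
           tag_str(group, element), call. = FALSE)
    }
    i <- i + 1L
    item_prefix <- sprintf("%s[%d].", prefix, i)
    content_at <- at + 8L
    if (len == UNDEFINED_LEN) {
      # parse elements until the item delimitation tag
      inner_at <- content_at
      repeat {
        if (inner_at + 7L > end + 1L) stop("unterminated item", call. = FALSE)
        g <- read_u16(bytes, inner_at)
        e <- read_u16(bytes, inner_at + 2L)
        if (g == 0xFFFE && e == 0xE00D) { inner_at <- inner_at + 8L; break }
        parsed <- parse_one_element(bytes, inner_at, end, explicit,
                                    item_prefix, depth + 1L)
        if (recurse) rows[[length(rows) + 1L]] <- parsed$rows
        inner_at <- parsed$next_at
      }
      at <- inner_at
    } else {
      item_end <- as.integer(content_at + len - 1)
      if (item_end > end) stop("item overruns sequence", call. = FALSE)
      if (recurse) {
        inner_at <- content_at
        while (inner_at <= item_end) {
          parsed <- parse_one_element(bytes, inner_at, item_end, explicit,
                                      item_prefix, depth + 1L)
          rows[[length(rows) + 1L]] <- parsed$rows
          inner_at <- parsed$next_at
        }
      } else {
        # opaque fragment (e.g. encapsulated pixel data): index as a leaf
        rows[[length(rows) + 1L]] <-
          index_row(sub("\\.$", "", item_prefix), 0xFFFE, 0xE000, "OB",
                    at, content_at, len, item_end + 1L, depth + 1L)
      }
      at <- item_end + 1L
    }
  }
  list(rows = if (length(rows)) do.call(rbind, rows),
       content_end = as.integer(end + 1L), next_at = as.integer(end + 1L))
}

element_raw <- function(bytes, row) {
  if (nrow(row) == 0L || row$value_len[1] == 0) return(raw(0))
  bytes[row$value_offset[1]:(row$value_offset[1] + row$value_len[1] - 1)]
}

element_text <- function(bytes, row) {
  if (nrow(row) == 0L) return(NA_character_)
  v <- element_raw(bytes, row)
  # strip trailing padding (NUL for UI, space for text VRs) before
  # rawToChar, which rejects embedded nuls
  while (length(v) && v[length(v)] %in% as.raw(c(0L, 32L))) {
    v <- v[-length(v)]
  }
  tryCatch(rawToChar(v), error = function(e) NA_character_)
}

#' Fetch a dataset value by tag
#'
#' @param dcm a `dicom_file` from [read_dicom()].
#' @param tag tag string like `"(0020,000E)"`.
#' @param meta look in the file-meta group instead of the main dataset.
#' @return The element's text value with trailing padding stripped, or
#'   `NA` if the tag is absent.
#' @export
dcm_value <- function(dcm, tag, meta = FALSE) {
  idx <- if (meta) dcm$meta else dcm$dataset
  element_text(dcm$bytes, idx[idx$path == tag & idx$depth == 0L, ])
}

#' @export
print.dicom_file <- function(x, ...) {
  cat("<dicom_file> ", x$path %||% "<bytes>", "\n",
      "  transfer syntax: ", x$transfer_syntax, "\n",
      "  meta elements: ", nrow(x$meta),
      ";  dataset elements: ", nrow(x$dataset), "\n", sep = "")
  invisible(x)
}
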