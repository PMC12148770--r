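#' Scan a directory for DICOM files
#'
#' Walks `root` (recursively by default — zipped exports usually unpack
#' into nested folders), probes every regular file for the Part-10
#' preamble magic regardless of extension, parses headers, and applies an
#' optional modality filter.  Parsing problems never abort the scan: a
#' file that cannot be read is recorded with `parse_ok = FALSE` and a
#' `skip_reason`; a parseable file outside the modality filter keeps
#' `parse_ok = TRUE` but is taken out of scope with reason
#' `"modality filtered"`.
#'
#' @param root directory to scan; must exist.
#' @param modalities optional character vector of modalities to keep.
#'   Tokens are case-insensitive; `"PET"` is accepted for DICOM `"PT"`,
#'   and `"4DCT"` for `"CT"` (4DCT is an acquisition mode, not a DICOM
#'   modality — see [remap_options()] for the grouping flag it implies).
#'   `NULL` keeps every modality.
#' @param recurse descend into subdirectories (default `TRUE`).
#' @return A data frame of file records (one row per file probed, sorted
#'   by path): `path`, `modality`, `series_uid`, `sop_uid`,
#'   `frame_of_reference_uid`, `series_description`, `parse_ok`,
#'   `skip_reason`, `in_scope`.  The scanned root is kept in
#'   `attr(, "root")`.
#' @examples
#' \dontrun{
#' recs <- scan_directory("exports/", modalities = c("CT", "MR"))
#' table(recs$modality, recs$in_scope)
#' }
#' @export
scan_directory <- function(root, modalities = NULL, recurse = TRUE) {
  if (length(root) != 1L || !dir.exists(root)) {
    stop("input directory '", root, "' does not exist", call. = FALSE)
  }
  filter <- normalize_modalities(modalities)
  files <- sort(list.files(root, recursive = recurse, full.names = TRUE))
  files <- files[file.exists(files) & !dir.exists(files)]

  recs <- lapply(files, function(f) scan_one_file(f, filter))
  recs <- if (length(recs)) do.call(rbind, recs) else empty_records()
  recs <- recs[order(recs$path), , drop = FALSE]
  rownames(recs) <- NULL
  recs$in_scope <- recs$parse_ok & is.na(recs$skip_reason)
  attr(recs, "root") <- root
  recs
}

empty_records <- function() {
  data.frame(path = character(), modality = character(),
             series_uid = character(), sop_uid = character(),
             frame_of_reference_uid = character(),
             series_description = character(),
             parse_ok = logical(), skip_reason = character(),
             stringsAsFactors = FALSE)
}

scan_one_file <- function(path, filter) {
  rec <- data.frame(path = path, modality = NA_character_,
                    series_uid = NA_character_, sop_uid = NA_character_,
                    frame_of_reference_uid = NA_character_,
                    series_description = NA_character_,
                    parse_ok = FALSE, skip_reason = NA_character_,
                    stringsAsFactors = FALSE)
  if (!has_dicom_magic(path)) {
    rec$skip_reason <- "not a DICOM file"
    return(rec)
  }
  dcm <- tryCatch(read_dicom(path), error = function(e) e)
  if (inherits(dcm, "error")) {
    rec$skip_reason <- paste("unparseable:", conditionMessage(dcm))
    return(rec)
  }
  rec$modality <- dcm_value(dcm, "(0008,0060)")
  rec$series_uid <- dcm_value(dcm, TAG_SERIES_UID)
  rec$sop_uid <- dcm_value(dcm, TAG_SOP_INSTANCE_UID)
  rec$frame_of_reference_uid <- dcm_value(dcm, TAG_FRAME_OF_REFERENCE)
  rec$series_description <- dcm_value(dcm, "(0008,103E)")
  if (is.na(rec$series_uid) || is.na(rec$sop_uid) ||
      !validate_uid(rec$series_uid) || !validate_uid(rec$sop_uid)) {
    rec$skip_reason <- "missing or invalid series/SOP UID"
    return(rec)
  }
  rec$parse_ok <- TRUE
  if (!is.null(filter) && !(rec$modality %in% filter)) {
    rec$skip_reason <- "modality filtered"
  }
  rec
}

has_dicom_magic <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n < 132) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 132)
  length(head) == 132L && rawToChar(head[129:132]) == "DICM"
}

#' Normalise user modality tokens to DICOM modality codes
#'
#' @param modalities character vector of user tokens (`"CT"`, `"4DCT"`,
#'   `"MR"`, `"MRI"`, `"PET"`, `"PT"`; case-insensitive) or `NULL`.
#' @return Character vector of DICOM modality codes, or `NULL`.
#' @export
normalize_modalities <- function(modalities) {
  if (is.null(modalities) || !length(modalities)) return(NULL)
  map <- c(CT = "CT", "4DCT" = "CT", MR = "MR", MRI = "MR",
           PET = "PT", PT = "PT")
  tok <- toupper(trimws(modalities))
  bad <- setdiff(tok, names(map))
  if (length(bad)) {
    stop("unknown modality token(s): ", paste(bad, collapse = ", "),
         " (expected CT, 4DCT, MR, PET)", call. = FALSE)
  }
  unique(unname(map[tok]))
}

#' Group scanned files into series
#'
#' Step one of the rewrite pipeline: partition in-scope records by Series
#' Instance UID.  Every in-scope record lands in exactly one group.  If
#' members of one series disagree on the Frame of Reference UID (real
#' exports are occasionally inconsistent) the group carries the most
#' frequent value and a warning is emitted.
#'
#' @param records data frame from [scan_directory()].
#' @return A list of `series_group` objects (sorted by series UID), each
#'   with `series_uid`, `modality`, `frame_of_reference_uid` (`NA` when
#'   the series has none) and `members` (the record rows, path-sorted).
#' @export
group_by_series <- function(records) {
  recs <- records[records$parse_ok & is.na(records$skip_reason), ,
                  drop = FALSE]
  if (nrow(recs) == 0L) return(list())
  groups <- lapply(split(recs, recs$series_uid), function(m) {
    m <- m[order(m$path), , drop = FALSE]
    fors <- m$frame_of_reference_uid[!is.na(m$frame_of_reference_uid)]
    for_uid <- NA_character_
    if (length(fors)) {
      tab <- sort(table(fors), decreasing = TRUE)
      for_uid <- names(tab)[1]
      if (length(tab) > 1L) {
        warning("series ", m$series_uid[1], " has ", length(tab),
                " distinct frame-of-reference UIDs; using the most ",
                "frequent (", for_uid, ")", call. = FALSE)
      }
    }
    structure(list(series_uid = m$series_uid[1], modality = m$modality[1],
                   frame_of_reference_uid = for_uid, members = m),
              class = "series_group")
  })
  groups[order(names(groups))]
}

#' Index series groups by frame of reference
#'
#' Treatment planning systems auto-register everything that shares one
#' Frame of Reference UID; this mapping is what the 4DCT-aware remap rule
#' operates on.
#'
#' @param groups list of `series_group` objects from [group_by_series()].
#' @return List with `by_for` (named list: FoR UID -> the groups bearing
#'   it) and `no_for` (groups without a frame of reference).
#' @export
group_by_frame_of_reference <- function(groups) {
  has_for <- vapply(groups, function(g) !is.na(g$frame_of_reference_uid),
                    logical(1))
  keys <- vapply(groups[has_for], `[[`, character(1),
                 "frame_of_reference_uid")
  by_for <- split(groups[has_for], keys)
  list(by_for = by_for[order(names(by_for))],
       no_for = unname(groups[!has_for]))
}

#' @export
print.series_group <- function(x, ...) {
  cat("<series_group> ", x$modality, " series ", x$series_uid, "\n",
      "  files: ", nrow(x$members),
      "  frame of reference: ", x$frame_of_reference_uid, "\n", sep = "")
  invisible(x)
}
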