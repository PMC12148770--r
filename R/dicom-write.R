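# DICOM Part-10 element encoding and file writing.  The fixture generator
# writes whole files (always Explicit VR Little Endian); the rewriter uses
# encode_element() to splice single replacement elements into otherwise
# untouched byte streams, matching the source transfer syntax.

pad_value <- function(vr, value) {
  if (length(value) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L)
           else if (vr %in% STRING_VRS) as.raw(32L)
           else as.raw(0L)
    value <- c(value, pad)
  }
  value
}

value_to_raw <- function(vr, value) {
  if (is.raw(value)) return(value)
  if (vr %in% c("US")) {
    return(do.call(c, lapply(as.integer(value), u16_le)))
  }
  if (vr %in% c("UL")) {
    return(do.call(c, lapply(as.numeric(value), u32_le)))
  }
  charToRaw(paste(as.character(value), collapse = "\\"))
}

encode_element <- function(group, element, vr, value, explicit = TRUE) {
  value <- pad_value(vr, value_to_raw(vr, value))
  len <- length(value)
  tag <- c(u16_le(group), u16_le(element))
  if (explicit) {
    if (vr %in% LONG_VRS) {
      c(tag, charToRaw(vr), raw(2), u32_le(len), value)
    } else {
      if (len > 65534L) stop("value too long for short VR ", vr, call. = FALSE)
      c(tag, charToRaw(vr), u16_le(len), value)
    }
  } else {
    c(tag, u32_le(len), value)
  }
}

el <- function(group, element, vr, value) {
  list(group = group, element = element, vr = vr, value = value)
}

# Assemble a Part-10 file from a list of el() entries (main dataset tags
# only; file meta is derived).  Elements are sorted into tag order as the
# standard requires.  Always Explicit VR Little Endian.
write_dicom_file <- function(elements, path,
                             implementation_uid = "2.25.424242424242") {
  ord <- order(vapply(elements, `[[`, 0, "group"),
               vapply(elements, `[[`, 0, "element"))
  elements <- elements[ord]
  get_val <- function(g, e) {
    for (x in elements) if (x$group == g && x$element == e) return(x$value)
    NULL
  }
  sop_class <- get_val(0x0008, 0x0016)
  sop_uid <- get_val(0x0008, 0x0018)
  if (is.null(sop_class) || is.null(sop_uid)) {
    stop("dataset needs SOPClassUID and SOPInstanceUID", call. = FALSE)
  }

  meta_els <- list(
    el(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    el(0x0002, 0x0002, "UI", sop_class),
    el(0x0002, 0x0003, "UI", sop_uid),
    el(0x0002, 0x0010, "UI", TS_EXPLICIT_LE),
    el(0x0002, 0x0012, "UI", implementation_uid)
  )
  meta_body <- do.call(c, lapply(meta_els, function(x) {
    encode_element(x$group, x$element, x$vr, x$value, explicit = TRUE)
  }))
  meta <- c(encode_element(0x0002, 0x0000, "UL", length(meta_body)),
            meta_body)

  body <- do.call(c, lapply(elements, function(x) {
    encode_element(x$group, x$element, x$vr, x$value, explicit = TRUE)
  }))

  out <- c(raw(128), charToRaw("DICM"), meta, body)
  atomic_write(out, path)
  invisible(path)
}

#' Write bytes atomically
#'
#' Writes to a temporary sibling file and renames it over the destination,
#' so an interrupted run never leaves a truncated DICOM file — the failure
#' mode that makes manual DICOM editing hazardous.
#'
#' @param bytes raw vector to write.
#' @param dest destination path; its directory must exist and be writable.
#' @return `dest`, invisibly.  On any failure the temporary file is
#'   removed and the original destination is left untouched.
#' @export
atomic_write <- function(bytes, dest) {
  tmp <- tempfile(pattern = paste0(".", basename(dest), "."),
                  tmpdir = dirname(dest))
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp), add = TRUE)
  con <- file(tmp, "wb")
  tryCatch({
    writeBin(bytes, con)
    close(con)
  }, error = function(e) {
    try(close(con), silent = TRUE)
    stop("write failed for '", dest, "': ", conditionMessage(e),
         call. = FALSE)
  })
  # file.rename warns and returns FALSE on failure; the error below is
  # the single report
  if (!suppressWarnings(file.rename(tmp, dest))) {
    stop("could not move temporary file over '", dest, "'", call. = FALSE)
  }
  ok <- TRUE
  invisible(dest)
}
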