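# Unzip support: zipped site exports are expanded in place before
# scanning.  Extraction uses R's internal unzip; a minimal store-only zip
# *writer* is included as test plumbing so round-trip equivalence can be
# exercised without external tooling.

#' Extract zip archives under a directory
#'
#' Finds every `.zip` under `root` and expands it beside itself,
#' preserving the archive's internal structure — the optional first step
#' of a run, so zipped exports can be processed without manual
#' extraction.  A corrupt archive is skipped with a warning; an archive
#' containing traversal entries (`../` or absolute paths) is rejected
#' outright.
#'
#' @param root directory to search; must exist.
#' @param delete_after remove each archive after successful extraction
#'   (default `FALSE`: keeping the archive is the safer default).
#' @param recurse search subdirectories too.
#' @return An `extraction_result`: `archives_found`, `files_extracted`,
#'   `destination`, and the per-archive outcomes in `details`.
#' @export
extract_archives <- function(root, delete_after = FALSE, recurse = TRUE) {
  if (!dir.exists(root)) {
    stop("input directory '", root, "' does not exist", call. = FALSE)
  }
  zips <- sort(list.files(root, pattern = "\\.zip$", ignore.case = TRUE,
                          recursive = recurse, full.names = TRUE))
  extracted <- 0L
  details <- list()
  for (z in zips) {
    res <- tryCatch({
      entries <- unzip(z, list = TRUE)
      names_ <- entries$Name
      if (any(grepl("(^|/)\\.\\.(/|$)", names_) | grepl("^([A-Za-z]:)?/",
                                                        names_))) {
        stop("archive contains path-traversal entries", call. = FALSE)
      }
      got <- unzip(z, exdir = dirname(z))
      if (delete_after) unlink(z)
      length(got)
    }, error = function(e) e, warning = function(w) {
      simpleError(conditionMessage(w))
    })
    if (inherits(res, "error")) {
      warning("skipping archive '", z, "': ", conditionMessage(res),
              call. = FALSE)
      details[[z]] <- conditionMessage(res)
    } else {
      extracted <- extracted + res
      details[[z]] <- sprintf("extracted %d file(s)", res)
    }
  }
  structure(list(archives_found = length(zips),
                 files_extracted = extracted,
                 destination = root, details = details),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat("<extraction_result> ", x$archives_found, " archive(s), ",
      x$files_extracted, " file(s) extracted under ", x$destination,
      "\n", sep = "")
  invisible(x)
}

# ---- store-only zip writer (test plumbing) --------------------------------

crc32_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (is.null(crc32_env$tab)) {
    poly <- -306674912L  # 0xEDB88320 as signed 32-bit
    tab <- integer(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8) {
        c <- if (bitwAnd(c, 1L) != 0L) {
          bitwXor(bitwShiftR(c, 1L), poly)
        } else bitwShiftR(c, 1L)
      }
      tab[n + 1L] <- c
    }
    crc32_env$tab <- tab
  }
  crc32_env$tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  c <- -1L
  for (b in as.integer(bytes)) {
    c <- bitwXor(bitwShiftR(c, 8L), tab[bitwAnd(bitwXor(c, b), 255L) + 1L])
  }
  bitwXor(c, -1L)  # signed 32-bit
}

#' Zip a directory (stored, uncompressed)
#'
#' Minimal deterministic zip writer used to build archive fixtures in
#' tests; entry paths are relative to `dir` and timestamps are fixed, so
#' the same tree always produces the same archive.
#'
#' @param dir directory whose contents to archive.
#' @param zipfile destination `.zip` path.
#' @return `zipfile`, invisibly.
#' @keywords internal
#' @export
zip_directory <- function(dir, zipfile) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = FALSE))
  con <- file(zipfile, "wb")
  on.exit(close(con))
  central <- list()
  offset <- 0
  dos_date <- u16_le(33L)  # 1980-01-01, fixed for determinism
  for (f in files) {
    data <- readBin(file.path(dir, f), "raw",
                    n = file.size(file.path(dir, f)))
    name <- charToRaw(f)
    crc <- u32_le(crc32(data))
    common <- c(u16_le(20L), u16_le(0L), u16_le(0L),   # version, flags, method
                u16_le(0L), dos_date,                   # time, date
                crc, u32_le(length(data)), u32_le(length(data)),
                u16_le(length(name)), u16_le(0L))       # name len, extra len
    local <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), common, name)
    writeBin(c(local, data), con)
    central[[f]] <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)), u16_le(20L),
                      common, u16_le(0L), u16_le(0L), u16_le(0L),
                      u32_le(0L), u32_le(offset), name)
    offset <- offset + length(local) + length(data)
  }
  cdir <- if (length(central)) do.call(c, central) else raw(0)
  writeBin(cdir, con)
  writeBin(c(as.raw(c(0x50, 0x4b, 0x05, 0x06)), u16_le(0L), u16_le(0L),
             u16_le(length(files)), u16_le(length(files)),
             u32_le(length(cdir)), u32_le(offset), u16_le(0L)), con)
  invisible(zipfile)
}
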