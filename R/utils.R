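# small shared helpers; little-endian byte codecs used by both the DICOM
# parser and the zip writer

`%||%` <- function(x, y) if (is.null(x)) y else x

u16_le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256))
}

u32_le <- function(x) {
  x <- as.numeric(x)
  if (x < 0) x <- x + 4294967296  # accept signed 32-bit input
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

read_u16 <- function(bytes, at) {
  as.integer(bytes[at]) + 256L * as.integer(bytes[at + 1L])
}

read_u32 <- function(bytes, at) {
  # returned as double: 0xFFFFFFFF does not fit an R integer
  as.numeric(bytes[at]) + 256 * as.numeric(bytes[at + 1L]) +
    65536 * as.numeric(bytes[at + 2L]) + 16777216 * as.numeric(bytes[at + 3L])
}

# "(0020,0052)" style tag rendering used in reports, diffs and plans
tag_str <- function(group, element) {
  sprintf("(%04X,%04X)", group, element)
}

is_group_length <- function(element) element == 0L

rel_path <- function(paths, root) {
  root <- sub("/+$", "", normalizePath(root, winslash = "/", mustWork = FALSE))
  p <- normalizePath(paths, winslash = "/", mustWork = FALSE)
  ifelse(startsWith(p, paste0(root, "/")),
         substring(p, nchar(root) + 2L), basename(p))
}
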