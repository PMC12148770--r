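# shared fixtures: studies are generated fresh into per-test temp dirs;
# pristine trees are copied (not regenerated) when a test needs the same
# study more than once

ALL_UID_TAGS <- c("(0020,0052)", "(0020,000E)", "(0008,0018)", "(0002,0003)")

tmp_study_dir <- function() {
  d <- tempfile("study-")
  dir.create(d)
  d
}

copy_tree <- function(from, to) {
  dir.create(to, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(from, recursive = TRUE)) {
    dest <- file.path(to, f)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    file.copy(file.path(from, f), dest)
  }
  to
}

# the tag set a run with these options must change, and nothing else
expected_tags <- function(options, has_for = TRUE) {
  tags <- character(0)
  if (options$change_frame_of_reference && has_for) {
    tags <- c(tags, "(0020,0052)")
  }
  if (options$change_series_uid) tags <- c(tags, "(0020,000E)")
  if (options$change_sop_uid) tags <- c(tags, "(0008,0018)", "(0002,0003)")
  sort(tags)
}

manifest_series_uids <- function(fx) {
  sort(vapply(fx$manifest$series, `[[`, character(1), "series_uid"))
}

manifest_sop_uids <- function(fx) {
  sort(unlist(lapply(fx$manifest$series, function(s) unlist(s$files)),
              use.names = FALSE))
}

# all UIDs a study contains (for freshness assertions)
manifest_all_uids <- function(fx) {
  c(fx$manifest$study_uid, fx$manifest$frame_of_reference_uid,
    manifest_series_uids(fx), manifest_sop_uids(fx))
}

read_bytes <- function(path) readBin(path, "raw", n = file.size(path))

tree_bytes <- function(root) {
  files <- sort(list.files(root, recursive = TRUE, full.names = FALSE))
  setNames(lapply(files, function(f) read_bytes(file.path(root, f))), files)
}
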