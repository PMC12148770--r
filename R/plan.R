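#' Options controlling which UID attributes are remapped
#'
#' Mirrors the three attribute checkboxes of the original tool plus the
#' 4DCT mode.  Changing the SOP Instance UID defaults to on; note that
#' new SOP UIDs orphan any RT plan / structure set that referenced the
#' old ones — those references are deliberately not repaired.
#'
#' @param change_frame_of_reference assign new Frame of Reference UIDs
#'   (0020,0052).
#' @param change_series_uid assign new Series Instance UIDs (0020,000E).
#' @param change_sop_uid assign new SOP Instance UIDs (0008,0018); the
#'   file-meta Media Storage SOP Instance UID (0002,0003) is kept in sync.
#' @param fourdct_mode treat CT series sharing one frame of reference as
#'   one rigid block (the respiratory phases of a 4DCT): they all receive
#'   the *same* new FoR UID instead of one per series, so the phases stay
#'   mutually registered while detaching from everything that keeps the
#'   old UID.
#' @return A `remap_options` object.
#' @export
remap_options <- function(change_frame_of_reference = FALSE,
                          change_series_uid = FALSE,
                          change_sop_uid = TRUE,
                          fourdct_mode = FALSE) {
  structure(list(change_frame_of_reference = isTRUE(change_frame_of_reference),
                 change_series_uid = isTRUE(change_series_uid),
                 change_sop_uid = isTRUE(change_sop_uid),
                 fourdct_mode = isTRUE(fourdct_mode)),
            class = "remap_options")
}

#' Build a UID remap plan for a set of series groups
#'
#' Decides, before any file is touched, the new UID for every targeted
#' attribute of every file:
#' * SOP Instance UID: one fresh UID per file.
#' * Series Instance UID: one fresh UID per series; all files of a series
#'   move together.
#' * Frame of Reference UID, 4DCT mode off: one fresh UID per series —
#'   every series is unlinked from every other.
#' * Frame of Reference UID, 4DCT mode on: CT series that shared an
#'   original FoR share one fresh UID (the phases stay registered to each
#'   other); non-CT series still get per-series UIDs.
#'
#' Every new UID is freshly generated, pairwise distinct, and distinct
#' from every UID seen in the input.
#'
#' @param groups list of `series_group` objects from [group_by_series()].
#' @param options a [remap_options()] object.
#' @param uid_source a UID generator closure from [uid_generator()].
#' @return A `remap_plan`: `for_map` (old FoR UID or series UID ->
#'   new FoR UID), `for_by_series` (series UID -> new FoR UID, the form
#'   the rewriter consumes), `series_map`, `sop_map`, `options`, and the
#'   input tally `n_files` / `n_series`.
#' @export
build_plan <- function(groups, options = remap_options(),
                       uid_source = uid_generator()) {
  stopifnot(inherits(options, "remap_options"))
  if (!length(groups)) {
    stop("no series in scope: nothing to plan", call. = FALSE)
  }

  old_uids <- unlist(lapply(groups, function(g) {
    c(g$series_uid, g$frame_of_reference_uid, g$members$sop_uid,
      g$members$frame_of_reference_uid)
  }), use.names = FALSE)
  old_uids <- unique(old_uids[!is.na(old_uids)])
  fresh <- function() {
    for (i in 1:100) {
      u <- uid_source()
      if (!(u %in% old_uids)) return(u)
    }
    stop("UID generator failed to produce a fresh value", call. = FALSE)
  }

  series_uids <- vapply(groups, `[[`, character(1), "series_uid")

  series_map <- character(0)
  if (options$change_series_uid) {
    series_map <- setNames(vapply(series_uids, function(s) fresh(),
                                  character(1)), series_uids)
  }

  sop_map <- character(0)
  if (options$change_sop_uid) {
    sops <- sort(unlist(lapply(groups, function(g) g$members$sop_uid),
                        use.names = FALSE))
    sop_map <- setNames(vapply(sops, function(s) fresh(), character(1)),
                        sops)
  }

  for_map <- character(0)
  for_by_series <- character(0)
  if (options$change_frame_of_reference) {
    has_for <- vapply(groups, function(g) !is.na(g$frame_of_reference_uid),
                      logical(1))
    shared_keys <- character(0)
    if (options$fourdct_mode) {
      is_ct <- vapply(groups, function(g) identical(g$modality, "CT"),
                      logical(1))
      shared_keys <- sort(unique(vapply(groups[has_for & is_ct],
                                        `[[`, character(1),
                                        "frame_of_reference_uid")))
      for (key in shared_keys) for_map[key] <- fresh()
    }
    for (g in groups[has_for]) {
      old_for <- g$frame_of_reference_uid
      if (old_for %in% shared_keys) {
        for_by_series[g$series_uid] <- for_map[[old_for]]
      } else {
        new_for <- fresh()
        for_map[g$series_uid] <- new_for
        for_by_series[g$series_uid] <- new_for
      }
    }
  }

  structure(list(for_map = for_map, for_by_series = for_by_series,
                 series_map = series_map, sop_map = sop_map,
                 options = options,
                 n_series = length(groups),
                 n_files = sum(vapply(groups, function(g) nrow(g$members),
                                      integer(1)))),
            class = "remap_plan")
}

#' Summarise a remap plan
#'
#' Deterministic human-readable rendering of what a plan will change;
#' this is what `--dry-run` prints.
#'
#' @param plan a `remap_plan` from [build_plan()].
#' @return Character vector of summary lines.
#' @export
plan_summary <- function(plan) {
  stopifnot(inherits(plan, "remap_plan"))
  o <- plan$options
  lines <- sprintf("remap plan: %d file(s) in %d series", plan$n_files,
                   plan$n_series)
  lines <- c(lines, sprintf(
    "  frame of reference UIDs: %s",
    if (o$change_frame_of_reference) {
      sprintf("%d new value(s)%s", length(unique(plan$for_map)),
              if (o$fourdct_mode) " [4DCT mode: shared across co-registered CT]"
              else " [one per series]")
    } else "unchanged"))
  lines <- c(lines, sprintf(
    "  series instance UIDs: %s",
    if (o$change_series_uid) sprintf("%d new value(s)", length(plan$series_map))
    else "unchanged"))
  lines <- c(lines, sprintf(
    "  SOP instance UIDs: %s",
    if (o$change_sop_uid) {
      sprintf("%d new value(s) (+ file-meta Media Storage SOP Instance UID)",
              length(plan$sop_map))
    } else "unchanged"))
  lines
}

#' @export
print.remap_plan <- function(x, ...) {
  cat(plan_summary(x), sep = "\n")
  invisible(x)
}

#' @export
print.remap_options <- function(x, ...) {
  cat("<remap_options>",
      sprintf("frame_of_reference=%s", x$change_frame_of_reference),
      sprintf("series=%s", x$change_series_uid),
      sprintf("sop=%s", x$change_sop_uid),
      sprintf("fourdct=%s", x$fourdct_mode), "\n")
  invisible(x)
}
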