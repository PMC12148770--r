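# Synthetic DICOM study generator.
#
# Emulates the two study layouts the tool is aimed at: a multi-series
# brain MR study whose series all share one frame of reference (the
# stereotactic-radiosurgery case), and a free-breathing CT plus
# multi-phase 4DCT sharing one frame of reference (the respiratory-
# correlated simulation case), plus a PET variant for modality-filter
# testing.  Files are small but fully valid Part-10 (Explicit VR Little
# Endian) with deterministic, seeded UIDs and pixel noise; a JSON
# manifest of every generated UID is written beside the study so tests
# can build expectations without re-parsing.

with_private_rng <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed, kind = "Mersenne-Twister")
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

make_pixels <- function(rows, cols, slice) {
  # diagonal gradient plus seeded noise, 16-bit little endian; content is
  # irrelevant to the tool but must survive byte-preservation checks
  grad <- outer(seq_len(rows), seq_len(cols), function(r, c) {
    (r + c + slice) * 7L
  })
  v <- as.integer(grad) + sample.int(50L, rows * cols, replace = TRUE)
  as.raw(rbind(v %% 256L, v %/% 256L))
}

make_study <- function(dir, modality, descriptions, n_slices, seed,
                       rows = 16L, cols = 16L, slice_spacing = 2.5,
                       patient = "Synthetic^Fixture", patient_id = "SYN001") {
  stopifnot(n_slices >= 1L, rows >= 1L, cols >= 1L)
  n_series <- length(descriptions)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- uid_generator(seed = seed)
  study_uid <- gen()
  for_uid <- gen()
  sop_class <- SOP_CLASS_UID[[modality]]

  series_manifest <- list()
  with_private_rng(seed, {
    for (s in seq_len(n_series)) {
      series_uid <- gen()
      sdir <- file.path(dir, sprintf("series_%02d", s))
      dir.create(sdir, showWarnings = FALSE)
      files <- list()
      for (i in seq_len(n_slices)) {
        sop_uid <- gen()
        fname <- sprintf("slice_%03d.dcm", i)
        elements <- list(
          el(0x0008, 0x0008, "CS", c("ORIGINAL", "PRIMARY", "AXIAL")),
          el(0x0008, 0x0016, "UI", sop_class),
          el(0x0008, 0x0018, "UI", sop_uid),
          el(0x0008, 0x0020, "DA", "20240101"),
          el(0x0008, 0x0030, "TM", "120000"),
          el(0x0008, 0x0060, "CS", modality),
          el(0x0008, 0x103E, "LO", descriptions[s]),
          el(0x0010, 0x0010, "PN", patient),
          el(0x0010, 0x0020, "LO", patient_id),
          el(0x0018, 0x0050, "DS", format(slice_spacing)),
          el(0x0020, 0x000D, "UI", study_uid),
          el(0x0020, 0x000E, "UI", series_uid),
          el(0x0020, 0x0011, "IS", as.character(s)),
          el(0x0020, 0x0013, "IS", as.character(i)),
          el(0x0020, 0x0032, "DS",
             c("0", "0", format((i - 1L) * slice_spacing))),
          el(0x0020, 0x0037, "DS", c("1", "0", "0", "0", "1", "0")),
          el(0x0020, 0x0052, "UI", for_uid),
          el(0x0028, 0x0002, "US", 1L),
          el(0x0028, 0x0004, "CS", "MONOCHROME2"),
          el(0x0028, 0x0010, "US", rows),
          el(0x0028, 0x0011, "US", cols),
          el(0x0028, 0x0030, "DS", c("1", "1")),
          el(0x0028, 0x0100, "US", 16L),
          el(0x0028, 0x0101, "US", 16L),
          el(0x0028, 0x0102, "US", 15L),
          el(0x0028, 0x0103, "US", 0L),
          el(0x7FE0, 0x0010, "OW", make_pixels(rows, cols, i))
        )
        write_dicom_file(elements, file.path(sdir, fname))
        files[[file.path(sprintf("series_%02d", s), fname)]] <- sop_uid
      }
      series_manifest[[s]] <- list(series_uid = series_uid,
                                   modality = modality,
                                   description = descriptions[s],
                                   files = files)
    }
  })

  manifest <- list(study_uid = study_uid,
                   frame_of_reference_uid = for_uid,
                   modality = modality, n_series = n_series,
                   n_slices = n_slices, seed = seed,
                   series = series_manifest)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(structure(list(dir = dir, manifest = manifest),
                      class = "fixture_study"))
}

#' Generate a synthetic multi-series brain MR study
#'
#' All series (alternating T1 / T2-FLAIR descriptions) share one Study
#' and one Frame of Reference UID — the layout in which consecutively
#' acquired MR sequences arrive inherently co-registered and motion
#' between scans cannot be corrected until the frame of reference is
#' broken.
#'
#' @param dir output directory (created if needed).
#' @param n_series,n_slices study shape; both at least 1.
#' @param seed integer; fixes every UID and all pixel noise, so the same
#'   seed reproduces the identical study.
#' @param rows,cols image matrix size (kept small by default; pixel
#'   content is irrelevant to UID manipulation).
#' @return Invisibly, a `fixture_study` with `dir` and the UID
#'   `manifest` (also written as `manifest.json` in `dir`).
#' @export
make_mr_study <- function(dir, n_series = 3L, n_slices = 4L, seed = 1L,
                          rows = 16L, cols = 16L) {
  stopifnot(n_series >= 1L)
  desc <- rep(c("T1 post", "T2 FLAIR", "T1 pre", "T2"),
              length.out = n_series)
  make_study(dir, "MR", desc, n_slices, seed, rows = rows, cols = cols)
}

#' Generate a synthetic 4DCT study (plus optional free-breathing CT)
#'
#' Respiratory phase series ("0%", "10%", ...) and, when requested, a
#' free-breathing helical CT — all sharing one Frame of Reference UID,
#' as simulators export them.  This is the layout whose unlinking needs
#' care: the phases must keep a common (new) frame of reference while
#' the link to the free-breathing scan can be broken.
#'
#' @param dir output directory.
#' @param n_phases number of respiratory phase series, at least 2.
#' @param n_slices slices per series.
#' @param include_free_breathing add the free-breathing series.
#' @param seed integer; fixes every UID and all pixel noise.
#' @param rows,cols image matrix size.
#' @return Invisibly, a `fixture_study` (see [make_mr_study()]).
#' @export
make_4dct_study <- function(dir, n_phases = 10L, n_slices = 5L,
                            include_free_breathing = TRUE, seed = 7L,
                            rows = 16L, cols = 16L) {
  stopifnot(n_phases >= 2L)
  desc <- sprintf("4DCT %d%%", round(seq(0, 90, length.out = n_phases)))
  if (include_free_breathing) desc <- c(desc, "Free Breathing CT")
  make_study(dir, "CT", desc, n_slices, seed, rows = rows, cols = cols)
}

#' Generate a synthetic PET study
#'
#' Modality `"PT"` variant of [make_mr_study()], for modality-filter
#' testing (e.g. PET/CT folders where only one modality should change).
#'
#' @inheritParams make_mr_study
#' @export
make_pet_study <- function(dir, n_series = 1L, n_slices = 4L, seed = 3L,
                           rows = 16L, cols = 16L) {
  stopifnot(n_series >= 1L)
  desc <- rep("PET WB", n_series)
  make_study(dir, "PT", desc, n_slices, seed, rows = rows, cols = cols)
}

#' @export
print.fixture_study <- function(x, ...) {
  m <- x$manifest
  cat("<fixture_study> ", m$modality, " study: ", m$n_series,
      " series x ", m$n_slices, " slice(s) under ", x$dir, "\n", sep = "")
  invisible(x)
}
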