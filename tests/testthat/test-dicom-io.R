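test_that("written files round-trip through the parser with their UIDs intact", {
  d <- tmp_study_dir()
  fx <- make_mr_study(d, n_series = 1, n_slices = 1, seed = 21)
  f <- list.files(d, pattern = "\\.dcm$", recursive = TRUE,
                  full.names = TRUE)
  expect_length(f, 1L)
  dcm <- read_dicom(f)
  expect_identical(dcm_value(dcm, "(0008,0060)"), "MR")
  expect_identical(dcm_value(dcm, "(0020,000E)"),
                   fx$manifest$series[[1]]$series_uid)
  expect_identical(dcm_value(dcm, "(0020,0052)"),
                   fx$manifest$frame_of_reference_uid)
  expect_identical(dcm_value(dcm, "(0002,0003)", meta = TRUE),
                   dcm_value(dcm, "(0008,0018)"))
  # file-meta group length must equal the byte count of the meta group
  gl <- dcm$meta[dcm$meta$element == 0L, ]
  meta_after_gl <- dcm$meta[dcm$meta$element != 0L, ]
  expect_equal(unlinkr:::read_u32(dcm$bytes, gl$value_offset),
               sum(meta_after_gl$end_offset - meta_after_gl$offset))
})

test_that("the parser agrees with pydicom on header values", {
  d <- tmp_study_dir()
  fx <- make_4dct_study(d, n_phases = 2, n_slices = 1, seed = 31)
  f <- list.files(d, pattern = "\\.dcm$", recursive = TRUE,
                  full.names = TRUE)[1]
  script <- paste(
    "import sys, pydicom",
    "ds = pydicom.dcmread(sys.argv[1])",
    "print(ds.Modality); print(ds.SeriesInstanceUID)",
    "print(ds.SOPInstanceUID); print(ds.FrameOfReferenceUID)",
    "print(int(ds.pixel_array.sum()))",
    sep = "\n")
  out <- system2("python", c("-", f), input = script, stdout = TRUE)
  dcm <- read_dicom(f)
  expect_identical(out[1], dcm_value(dcm, "(0008,0060)"))
  expect_identical(out[2], dcm_value(dcm, "(0020,000E)"))
  expect_identical(out[3], dcm_value(dcm, "(0008,0018)"))
  expect_identical(out[4], dcm_value(dcm, "(0020,0052)"))
  # pixel sum recomputed from the raw element bytes
  px <- dcm$dataset[dcm$dataset$group == 0x7FE0, ]
  v <- unlinkr:::element_raw(dcm$bytes, px)
  lo <- as.integer(v[seq(1, length(v), 2)])
  hi <- as.integer(v[seq(2, length(v), 2)])
  expect_identical(as.integer(out[5]), sum(lo + 256L * hi))
})

test_that("implicit VR little endian files are parsed and rewritten correctly", {
  d <- tmp_study_dir()
  make_mr_study(d, n_series = 1, n_slices = 1, seed = 41)
  f <- list.files(d, pattern = "\\.dcm$", recursive = TRUE,
                  full.names = TRUE)[1]
  fi <- file.path(d, "implicit.dcm")
  conv <- paste(
    "import sys, pydicom",
    "ds = pydicom.dcmread(sys.argv[1])",
    "ds.file_meta.TransferSyntaxUID = pydicom.uid.ImplicitVRLittleEndian",
    "ds.is_implicit_VR = True; ds.is_little_endian = True",
    "ds.save_as(sys.argv[2], enforce_file_format=True)",
    sep = "\n")
  system2("python", c("-", f, fi), input = conv)
  explicit <- read_dicom(f)
  implicit <- read_dicom(fi)
  expect_false(implicit$explicit)
  for (tag in c("(0008,0018)", "(0020,000E)", "(0020,0052)", "(0008,0060)")) {
    expect_identical(dcm_value(implicit, tag), dcm_value(explicit, tag))
  }

  # rewrite one UID in the implicit file; pydicom must see the new value
  new_sop <- generate_uid(1, seed = 99)
  rw <- unlinkr:::rewrite_file_bytes(
    read_bytes(fi), setNames(list(new_sop), "(0008,0018)"))
  writeBin(rw$bytes, fi)
  check <- paste(
    "import sys, pydicom",
    "ds = pydicom.dcmread(sys.argv[1])",
    "print(ds.SOPInstanceUID)",
    sep = "\n")
  expect_identical(system2("python", c("-", fi), input = check,
                           stdout = TRUE), new_sop)
})

test_that("sequence elements are indexed recursively with item paths", {
  d <- tmp_study_dir()
  # referenced-image sequence with two items, built from encoded elements
  item_body <- function(uid) {
    c(unlinkr:::encode_element(0x0008, 0x1150, "UI",
                               "1.2.840.10008.5.1.4.1.1.4"),
      unlinkr:::encode_element(0x0008, 0x1155, "UI", uid))
  }
  items <- do.call(c, lapply(c("1.2.3.4", "1.2.3.5"), function(u) {
    body <- item_body(u)
    c(unlinkr:::u16_le(0xFFFE), unlinkr:::u16_le(0xE000),
      unlinkr:::u32_le(length(body)), body)
  }))
  gen <- uid_generator(seed = 55)
  elements <- list(
    unlinkr:::el(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.4"),
    unlinkr:::el(0x0008, 0x0018, "UI", gen()),
    unlinkr:::el(0x0008, 0x0060, "CS", "MR"),
    unlinkr:::el(0x0008, 0x1140, "SQ", items),
    unlinkr:::el(0x0020, 0x000D, "UI", gen()),
    unlinkr:::el(0x0020, 0x000E, "UI", gen())
  )
  f <- file.path(d, "seq.dcm")
  unlinkr:::write_dicom_file(elements, f)
  dcm <- read_dicom(f)
  nested <- dcm$dataset[dcm$dataset$depth == 1L, ]
  expect_identical(nested$path,
                   c("(0008,1140)[1].(0008,1150)",
                     "(0008,1140)[1].(0008,1155)",
                     "(0008,1140)[2].(0008,1150)",
                     "(0008,1140)[2].(0008,1155)"))
  row <- nested[nested$path == "(0008,1140)[2].(0008,1155)", ]
  expect_identical(unlinkr:::element_text(dcm$bytes, row), "1.2.3.5")
  # pydicom agrees on the nested value
  out <- system2("python", c("-", f), input = paste(
    "import sys, pydicom",
    "ds = pydicom.dcmread(sys.argv[1])",
    "print(ds.ReferencedImageSequence[1].ReferencedSOPInstanceUID)",
    sep = "\n"), stdout = TRUE)
  expect_identical(out, "1.2.3.5")
})

test_that("non-DICOM and truncated inputs are rejected, not crashed on", {
  d <- tmp_study_dir()
  txt <- file.path(d, "note.txt")
  writeLines("not an image", txt)
  expect_error(read_dicom(txt), "DICM")
  expect_false(unlinkr:::has_dicom_magic(txt))

  trunc <- file.path(d, "trunc.dcm")
  make_mr_study(file.path(d, "s"), 1, 1, seed = 61)
  src <- list.files(file.path(d, "s"), pattern = "\\.dcm$",
                    recursive = TRUE, full.names = TRUE)[1]
  writeBin(read_bytes(src)[1:200], trunc)
  expect_error(read_dicom(trunc))
})

test_that("atomic_write never leaves a partial destination", {
  d <- tmp_study_dir()
  dest <- file.path(d, "out.bin")
  atomic_write(as.raw(1:10), dest)
  expect_identical(read_bytes(dest), as.raw(1:10))

  # failure path: renaming over an existing directory cannot succeed
  blocked <- file.path(d, "blocked")
  dir.create(blocked)
  expect_error(atomic_write(as.raw(1:4), blocked), "could not move")
  expect_true(dir.exists(blocked))          # destination untouched
  # and no temporary file left behind
  expect_identical(sort(list.files(d, all.files = TRUE, no.. = TRUE)),
                   c("blocked", "out.bin"))
})
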