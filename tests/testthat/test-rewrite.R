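test_that("an SOP-only rewrite changes exactly the SOP UID and its meta mirror", {
  d <- tmp_study_dir()
  fx <- make_mr_study(d, n_series = 1, n_slices = 5, seed = 19)
  before <- dicom_snapshot(d)
  recs <- scan_directory(d)
  plan <- build_plan(group_by_series(recs), remap_options(),
                     uid_generator(seed = 8))
  report <- apply_plan(plan, recs)

  expect_true(all(report$write_ok))
  expect_identical(attr(report, "totals")$files_changed, 5L)
  expect_true(all(vapply(report$tags_changed, identical, logical(1),
                         c("(0002,0003)", "(0008,0018)"))))

  after <- dicom_snapshot(d)
  diff <- diff_datasets(before, after)
  expect_setequal(unique(diff$tag), c("(0008,0018)", "(0002,0003)"))
  expect_identical(nrow(diff), 10L)  # two tags in each of 5 files

  # fresh, unique SOP UIDs; (0002,0003) equals (0008,0018); pixels intact
  recs2 <- scan_directory(d)
  sops <- recs2$sop_uid[recs2$in_scope]
  expect_length(unique(sops), 5L)
  expect_length(intersect(sops, manifest_sop_uids(fx)), 0L)
  for (f in recs2$path[recs2$in_scope]) {
    dcm <- read_dicom(f)
    expect_identical(dcm_value(dcm, "(0002,0003)", meta = TRUE),
                     dcm_value(dcm, "(0008,0018)"))
    px_before <- before[[rel_path <- unlinkr:::rel_path(f, d)]]
    px_after <- after[[rel_path]]
    expect_identical(px_after$digest[px_after$path == "(7FE0,0010)"],
                     px_before$digest[px_before$path == "(7FE0,0010)"])
  }
})

test_that("a no-op plan writes byte-identical copies to an output dir", {
  d <- tmp_study_dir()
  make_mr_study(file.path(d, "in"), n_series = 1, n_slices = 5, seed = 29)
  recs <- scan_directory(file.path(d, "in"))
  plan <- build_plan(group_by_series(recs),
                     remap_options(change_sop_uid = FALSE),
                     uid_generator(seed = 9))
  out <- file.path(d, "out")
  report <- apply_plan(plan, recs, output_dir = out)
  expect_true(all(report$write_ok))
  expect_true(all(lengths(report$tags_changed) == 0L))

  dcms <- list.files(file.path(d, "in"), pattern = "\\.dcm$",
                     recursive = TRUE)
  expect_setequal(list.files(out, recursive = TRUE), dcms)
  for (f in dcms) {
    expect_identical(read_bytes(file.path(out, f)),
                     read_bytes(file.path(d, "in", f)))
  }
})

test_that("a full three-attribute 4DCT rewrite conserves structure on disk", {
  d <- tmp_study_dir()
  fx <- make_4dct_study(d, n_phases = 10, n_slices = 2, seed = 7)
  recs <- scan_directory(d)
  sizes_before <- table(recs$series_uid[recs$in_scope])
  plan <- build_plan(group_by_series(recs),
                     remap_options(change_frame_of_reference = TRUE,
                                   change_series_uid = TRUE,
                                   fourdct_mode = TRUE),
                     uid_generator(seed = 10))
  report <- apply_plan(plan, recs)  # in place
  expect_true(all(report$write_ok))

  recs2 <- scan_directory(d)
  in2 <- recs2[recs2$in_scope, ]
  # same partition: 11 series of the same sizes, all-new series UIDs
  expect_identical(sort(as.integer(table(in2$series_uid))),
                   sort(as.integer(sizes_before)))
  expect_length(intersect(in2$series_uid, manifest_series_uids(fx)), 0L)
  # FoR count conserved (one before, one after) but value is new
  expect_length(unique(in2$frame_of_reference_uid), 1L)
  expect_false(unique(in2$frame_of_reference_uid) ==
                 fx$manifest$frame_of_reference_uid)
  # no file still carries any old UID
  expect_length(intersect(in2$sop_uid, manifest_sop_uids(fx)), 0L)
})

test_that("write failures are per-file, reported, and leave originals intact", {
  d <- tmp_study_dir()
  make_mr_study(d, n_series = 1, n_slices = 3, seed = 37)
  recs <- scan_directory(d)
  victim <- recs$path[recs$in_scope][2]
  original <- read_bytes(victim)
  plan <- build_plan(group_by_series(recs), remap_options(),
                     uid_generator(seed = 11))

  failing_writer <- function(bytes, dest) {
    if (dest == victim) stop("disk full (injected)")
    atomic_write(bytes, dest)
  }
  report <- apply_plan(plan, recs, writer = failing_writer)
  t <- attr(report, "totals")
  expect_identical(t$files_failed, 1L)
  expect_identical(t$files_changed + t$files_failed, sum(recs$in_scope))
  bad <- report[!report$write_ok, ]
  expect_identical(bad$path, victim)
  expect_match(bad$error, "injected")
  expect_identical(read_bytes(victim), original)     # untouched
  # the other files were rewritten
  ok <- report[report$write_ok, ]
  expect_true(all(vapply(ok$tags_changed, length, integer(1)) > 0L))
})

test_that("a file the plan does not cover yields a per-file error", {
  d <- tmp_study_dir()
  make_mr_study(file.path(d, "a"), n_series = 1, n_slices = 1, seed = 43)
  recs_a <- scan_directory(file.path(d, "a"))
  plan <- build_plan(group_by_series(recs_a), remap_options(),
                     uid_generator(seed = 12))
  make_mr_study(file.path(d, "b"), n_series = 1, n_slices = 1, seed = 44)
  recs_all <- scan_directory(d)
  report <- apply_plan(plan, recs_all)
  expect_identical(attr(report, "totals")$files_failed, 1L)
  expect_match(report$error[!report$write_ok], "not covered by plan")
})

test_that("rewrites preserve every untargeted element byte-for-byte", {
  # property over all eight flag combinations on one series
  d0 <- tmp_study_dir()
  make_mr_study(d0, n_series = 1, n_slices = 2, seed = 47)
  combos <- expand.grid(f = c(FALSE, TRUE), s = c(FALSE, TRUE),
                        p = c(FALSE, TRUE))
  for (i in seq_len(nrow(combos))) {
    d <- copy_tree(d0, tempfile("combo-"))
    o <- remap_options(change_frame_of_reference = combos$f[i],
                       change_series_uid = combos$s[i],
                       change_sop_uid = combos$p[i])
    recs <- scan_directory(d)
    plan <- build_plan(group_by_series(recs), o,
                       uid_generator(seed = 100 + i))
    before <- dicom_snapshot(d)
    apply_plan(plan, recs)
    diff <- diff_datasets(before, dicom_snapshot(d))
    expect_setequal(unique(diff$tag), expected_tags(o))
    expect_true(assert_only_changed(diff, expected_tags(o)))
  }
})
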