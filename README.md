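# unlinkr

Batch rewriting of the three DICOM attributes that control how a
treatment planning system (TPS) links image sets together:

| Attribute | Tag | Role |
|---|---|---|
| Frame of Reference UID | (0020,0052) | names a spatial coordinate system; image sets sharing it are treated as inherently co-registered |
| Series Instance UID | (0020,000E) | identifies one series (one MR sequence, one 4DCT phase) |
| SOP Instance UID | (0008,0018) | identifies one object/slice; mirrored in file meta as (0002,0003) |

In radiotherapy practice this "inherent registration" is often exactly
what must be broken: consecutively acquired MR sequences share one frame
of reference, so motion between them can never be corrected; a PET/CT
that needs two different rigid registrations must be imported twice with
distinct identities.  unlinkr scans a folder of DICOM Part-10 files,
groups them by series and frame of reference, assigns fresh
standards-conformant UIDs (`2.25.<decimal 128-bit integer>`, or a
registered root), and rewrites **only** the targeted tags — every other
byte, pixel data included, is preserved and a built-in differ proves it.

The delicate case is the 4DCT: a free-breathing CT and the respiratory
phase series of a 4DCT are exported sharing one frame of reference.  With
`fourdct_mode` the remapper assigns **one fresh frame-of-reference UID
per original value**, so all phases stay mutually registered while
detaching from everything that keeps the old UID; without it, every
series gets its own new UID and is unlinked from every other.  SOP UID
changes are on by default (and orphan RT plan / structure set references,
which are deliberately not repaired); the Study Instance UID is never
touched.

## Worked example

Unlink a simulated 4DCT folder (10 phases + free-breathing scan, 55
files, one shared frame of reference) while keeping the phases together:

```r
library(unlinkr)

fx <- make_4dct_study("sim", n_phases = 10, n_slices = 5, seed = 7)
before <- dicom_snapshot("sim")

run <- unlink_run("sim",
                  remap_options(change_frame_of_reference = TRUE,
                                fourdct_mode = TRUE),
                  modalities = "CT", seed = 2026)
print(run$plan)
#> remap plan: 55 file(s) in 11 series
#>   frame of reference UIDs: 1 new value(s) [4DCT mode: shared across co-registered CT]
#>   series instance UIDs: unchanged
#>   SOP instance UIDs: 55 new value(s) (+ file-meta Media Storage SOP Instance UID)
print(run$report)
#> <change_report> 55 file(s): 55 written, 0 failed
```

One new frame of reference for all 11 series (the 4DCT stays a rigid
block, unlinked from the originals left in the TPS), one fresh SOP UID
per file.  The verify differ confirms nothing else moved:

```r
diff <- diff_datasets(before, dicom_snapshot("sim"))
diff
#> <attribute_diff> 55 file(s) compared; 165 differing tag(s)
#>                       file         tag ...
#> 1  series_01/slice_001.dcm (0002,0003) ...
#> 2  series_01/slice_001.dcm (0008,0018) ...
#> 3  series_01/slice_001.dcm (0020,0052) ...
isTRUE(assert_only_changed(diff, c("(0020,0052)", "(0008,0018)",
                                   "(0002,0003)")))
#> [1] TRUE

recs <- scan_directory("sim")
unique(recs$frame_of_reference_uid[recs$in_scope])
#> [1] "2.25.310347415652692874820325772899840949458"
```

Exactly three tags differ per file — the frame of reference, the SOP
UID, and its file-meta mirror — 165 changes across 55 files, and the 11
series now share the single new FoR UID shown (the original was
`2.25.179748...`).

## Command line

A thin Rscript front end mirrors the original checkbox UI:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/unlink.R", package = "unlinkr"))')
Rscript $CLI run EXPORT_DIR --change-for --fourdct --modality CT --seed 1
Rscript $CLI run EXPORT_DIR --change-series --keep-sop --dry-run
Rscript $CLI run ZIPPED_DIR --unzip --modality MR --output-dir out/
Rscript $CLI verify BEFORE_DIR AFTER_DIR --allow '(0008,0018),(0002,0003)'
Rscript $CLI fixtures make-4dct --out sim --seed 7
```

`run` exits 0 on success, 1 if any file failed (per-file details in the
`--report` JSON), 2 if nothing was in scope.

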