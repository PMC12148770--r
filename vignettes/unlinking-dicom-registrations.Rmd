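---
title: "Unlinking DICOM image registrations by rewriting UID attributes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unlinking DICOM image registrations by rewriting UID attributes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unlinkr)
```

## Why rewrite UIDs at all

DICOM identifies things with UIDs — dotted-decimal strings of up to 64
characters.  Three of them control how a treatment planning system (TPS)
stitches image sets together:

* **Frame of Reference UID (0020,0052)** names a spatial coordinate
  system.  Image sets that share it are treated as *inherently
  co-registered*: the TPS aligns them rigidly, with no option to adjust.
* **Series Instance UID (0020,000E)** identifies one series — one MR
  sequence, one respiratory phase of a 4DCT.
* **SOP Instance UID (0008,0018)** identifies one object (one slice), and
  is mirrored in the Part-10 file meta header as the Media Storage SOP
  Instance UID (0002,0003).

The shared frame of reference is usually helpful, but it becomes a
hindrance in two recurring radiotherapy situations.  Consecutively
acquired MR sequences (T1, T2, FLAIR) of one study share a frame of
reference, so patient motion between sequences can never be corrected:
the TPS refuses to re-register what it considers already registered.  And
when the same image set must be registered twice to different anatomical
regions (for example a PET/CT matched once about the nasal cavity and
once about the neck), the only way to hold two rigid registrations at
once is to import a second copy of the images with new series — and
possibly new frame-of-reference — identities.

Assigning a *fresh* Frame of Reference UID "breaks" the implicit
registration and lets the planner register manually.  Doing that by hand
in a generic DICOM editor is risky: it is easy to edit additional
attributes unintentionally or corrupt a file outright.  unlinkr automates
exactly this narrow edit and then *proves* nothing else changed.

## The 4DCT consistency rule

The delicate case is respiration-correlated CT.  A simulation session
typically produces a free-breathing scan *and* a 4DCT reconstructed into
phase series (0%, 10%, ..., 90%), all sharing one frame of reference.  If
the phases are given independent new frames of reference they fall apart
as a 4D dataset; if nothing changes they stay pinned to the free-breathing
scan.

The rule implemented in [build_plan()] is keyed on the *original* frame
of reference:

* **4DCT mode off** — one fresh FoR UID per series.  After the run the
  number of distinct FoR UIDs equals the number of series: everything is
  unlinked from everything.
* **4DCT mode on** — one fresh FoR UID per *original* FoR value, applied
  to the CT series that shared it.  The phases remain mutually
  registered (the count of distinct FoR values is conserved), while the
  registration to anything that keeps the old UID — typically the copy
  still inside the TPS — is broken.

One documented caveat follows from the literal rule: a free-breathing CT
exported *into the same folder* as the 4DCT shares its original FoR and
therefore also its new one — the two stay linked to each other, though
both detach from the un-exported originals.  Separating them requires a
second pass over the free-breathing series alone.  Non-CT series in a
4DCT-mode run keep the per-series rule; the mode is an acquisition-mode
flag for CT, not a DICOM modality (there is no "4DCT" value of
(0008,0060)).

Series UID remapping is always per series, SOP remapping always per file;
only the frame-of-reference semantics depend on the mode.  Changing SOP
UIDs is on by default but orphans RT plan / structure set objects that
referenced the old instances — those references are deliberately *not*
repaired, and the Study Instance UID is never touched.

## The pipeline and its safety contract

A run is `extract_archives()` (optional) → `scan_directory()` →
`group_by_series()` → `build_plan()` → `apply_plan()`:

1. **Scan** probes every regular file for the Part-10 magic (extensions
   are not trusted), parses headers, and applies the modality filter.
   Unreadable files are recorded and skipped, never fatal.  Filtered
   files stay on disk untouched, bit for bit.
2. **Group** partitions in-scope files by Series Instance UID.  If a
   series disagrees internally about its frame of reference — real
   exports occasionally do — the majority value is used, with a warning.
3. **Plan** draws every replacement UID up front and checks freshness:
   no new UID may equal any UID seen anywhere in the input, and all new
   values are pairwise distinct.
4. **Apply** rewrites each file by *byte splicing*: the parser indexes
   element positions, replacement elements are encoded in the source
   transfer syntax, and every untargeted byte range is copied verbatim.
   Pixel data is never decoded.  When (0008,0018) changes, the file-meta
   mirror (0002,0003) and the meta group length are updated with it —
   files whose meta header disagrees with the dataset are rejected by
   many TPS importers.  Writes go to a temporary sibling file renamed
   over the destination, so an interrupted run cannot leave a truncated
   file.  In-place overwrite is the default; `output_dir` writes copies.

The verification layer ([dicom_snapshot()], [diff_datasets()],
[assert_only_changed()]) re-reads whole trees and compares every element
digest — file meta, nested sequence items (addressed by indexed tag
paths), and pixel data — so the claim "only the desired attributes
changed" is checked mechanically rather than by inspection in a viewer.
Group-length elements (gggg,0000) are excluded from snapshots: they are
derived encoding bookkeeping, and the file-meta group length legitimately
shifts when a replacement UID has a different byte length than the
original.

## UID generation

Replacement UIDs use the `2.25.<decimal 128-bit integer>` form the
standard reserves for UUID-derived identifiers, so no registered
organisation root is needed and the 64-character limit always holds
(5 + at most 39 digits).  A site with a registered root can pass it via
`uid_root`; the suffix entropy is shrunk to fit, and roots leaving fewer
than 64 bits of randomness are rejected.  Seeded generators draw from a
private RNG stream: the sequence is reproducible for testing and the
caller's RNG state is never disturbed.  Replacements are wholly fresh —
no structure of the old UID is preserved.

## What the synthetic studies emulate — and what they do not

The package generates its own test data (`make_mr_study()`,
`make_4dct_study()`, `make_pet_study()`): multi-series brain-MR-like
studies sharing one frame of reference, and free-breathing + multi-phase
4DCT layouts, as Explicit VR Little Endian Part-10 files with a seeded
UID manifest written alongside.  Pixel content is a small deterministic
gradient plus seeded noise (16×16 by default) — enough to make
byte-preservation checks meaningful, not anatomy.  The generated files
deliberately do not cover compressed transfer syntaxes, big-endian files,
RT structure sets / plans, private vendor blocks, or multi-frame objects;
passing tests demonstrate the remapping and verification logic, not
robustness against every encoding in the wild.  The parser itself accepts
Explicit and Implicit VR Little Endian (the unit tests convert fixtures
to implicit VR with an independent DICOM implementation to cover the
second path) and refuses other syntaxes explicitly rather than guessing.

Problem sizes in the test suite and the acceptance script are the study
shapes above (an 11-series, 55-file 4DCT folder at the largest); the
scaling-relevant loops are linear in file count and the 10,000-UID
uniqueness check runs in about a second.

## Numerical and design choices

* UID suffixes come from 128 random bits converted to decimal with exact
  base-2^16 → base-10^7 limb arithmetic (doubles never exceed 2^53), so
  renderings are exact, leading-zero-free, and platform independent.
* A generator closure keeps a seen-set and redraws on collision; with
  128-bit entropy this is unreachable in practice, but it makes the
  pairwise-distinct contract unconditional rather than probabilistic.
* Intra-series FoR ties are broken toward the most frequent value;
  groups and plan maps are built in sorted (series UID, path) order so
  reports and seeded runs are deterministic.
* A series that has no (0020,0052) is left without one when a FoR change
  is requested: inserting a new element would violate the
  only-targeted-attributes guarantee, and such series are already
  unlinked from everything.
* Zip extraction rejects archives with path-traversal entries and skips
  corrupt ones with a warning; archives are kept unless deletion is
  requested.
* Exit status of a run reflects the change report: `0` all written, `1`
  some files failed (the report says which and why), `2` nothing in
  scope.

## Known limitations

* Only uncompressed little-endian transfer syntaxes are processed;
  compressed exports must be decompressed upstream.
* References inside RT Plan / RT Structure Set / registration objects
  are not updated — by design the tool accepts broken associations when
  SOP UIDs change.
* The scanner requires the 128-byte preamble + `DICM` magic; legacy
  headerless implicit-VR files are reported as non-DICOM.
* Verification pairs files by relative path, which both in-place and
  copy modes preserve; renames between snapshots show up as
  added/removed files rather than diffs.
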