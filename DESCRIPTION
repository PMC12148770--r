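Package: unlinkr
Title: Break DICOM Image Registration Links by Rewriting UID Attributes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Batch manipulation of the three DICOM attributes that control
    how treatment planning systems link image sets: the Frame of Reference
    UID (0020,0052), the Series Instance UID (0020,000E) and the SOP
    Instance UID (0008,0018).  Scans a folder of DICOM Part-10 files,
    groups them by series and frame of reference, assigns fresh
    standards-conformant UIDs with 4DCT-aware consistency (all respiratory
    phases keep a common, but new, frame of reference), and rewrites only
    the targeted tags in place or into a copy, leaving every other byte of
    the file untouched.  Includes a tag-level dataset differ that proves
    only the requested attributes changed, an unzip step for zipped
    exports, and a synthetic study generator (brain MR, free-breathing CT
    plus 4DCT, PET) for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
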