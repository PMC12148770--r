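# Minimal data-element dictionary: the tags this tool reads, writes or
# names in reports, plus what implicit-VR parsing needs.  Unknown tags
# fall back to VR "UN".

TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

SOP_CLASS_UID <- c(
  CT = "1.2.840.10008.5.1.4.1.1.2",
  MR = "1.2.840.10008.5.1.4.1.1.4",
  PT = "1.2.840.10008.5.1.4.1.1.128"
)

TAG_SOP_INSTANCE_UID   <- "(0008,0018)"
TAG_SERIES_UID         <- "(0020,000E)"
TAG_FRAME_OF_REFERENCE <- "(0020,0052)"
TAG_MEDIA_STORAGE_SOP  <- "(0002,0003)"

dicom_dict <- local({
  d <- rbind(
    c(0x0002, 0x0001, "OB", "FileMetaInformationVersion"),
    c(0x0002, 0x0002, "UI", "MediaStorageSOPClassUID"),
    c(0x0002, 0x0003, "UI", "MediaStorageSOPInstanceUID"),
    c(0x0002, 0x0010, "UI", "TransferSyntaxUID"),
    c(0x0002, 0x0012, "UI", "ImplementationClassUID"),
    c(0x0002, 0x0013, "SH", "ImplementationVersionName"),
    c(0x0008, 0x0008, "CS", "ImageType"),
    c(0x0008, 0x0016, "UI", "SOPClassUID"),
    c(0x0008, 0x0018, "UI", "SOPInstanceUID"),
    c(0x0008, 0x0020, "DA", "StudyDate"),
    c(0x0008, 0x0030, "TM", "StudyTime"),
    c(0x0008, 0x0050, "SH", "AccessionNumber"),
    c(0x0008, 0x0060, "CS", "Modality"),
    c(0x0008, 0x103E, "LO", "SeriesDescription"),
    c(0x0010, 0x0010, "PN", "PatientName"),
    c(0x0010, 0x0020, "LO", "PatientID"),
    c(0x0018, 0x0050, "DS", "SliceThickness"),
    c(0x0020, 0x000D, "UI", "StudyInstanceUID"),
    c(0x0020, 0x000E, "UI", "SeriesInstanceUID"),
    c(0x0020, 0x0011, "IS", "SeriesNumber"),
    c(0x0020, 0x0013, "IS", "InstanceNumber"),
    c(0x0020, 0x0032, "DS", "ImagePositionPatient"),
    c(0x0020, 0x0037, "DS", "ImageOrientationPatient"),
    c(0x0020, 0x0052, "UI", "FrameOfReferenceUID"),
    c(0x0028, 0x0002, "US", "SamplesPerPixel"),
    c(0x0028, 0x0004, "CS", "PhotometricInterpretation"),
    c(0x0028, 0x0010, "US", "Rows"),
    c(0x0028, 0x0011, "US", "Columns"),
    c(0x0028, 0x0030, "DS", "PixelSpacing"),
    c(0x0028, 0x0100, "US", "BitsAllocated"),
    c(0x0028, 0x0101, "US", "BitsStored"),
    c(0x0028, 0x0102, "US", "HighBit"),
    c(0x0028, 0x0103, "US", "PixelRepresentation"),
    c(0x7FE0, 0x0010, "OW", "PixelData")
  )
  data.frame(group = strtoi(d[, 1]), element = strtoi(d[, 2]),
             vr = d[, 3], name = d[, 4], stringsAsFactors = FALSE)
})

dict_lookup_vr <- function(group, element) {
  hit <- dicom_dict$vr[dicom_dict$group == group &
                         dicom_dict$element == element]
  if (length(hit)) hit[1] else "UN"
}

tag_name <- function(tag) {
  m <- regmatches(tag, regexec("\\(([0-9A-Fa-f]{4}),([0-9A-Fa-f]{4})\\)", tag))[[1]]
  if (length(m) != 3L) return(NA_character_)
  hit <- dicom_dict$name[dicom_dict$group == strtoi(m[2], 16L) &
                           dicom_dict$element == strtoi(m[3], 16L)]
  if (length(hit)) hit[1] else NA_character_
}

# VRs that use the 4-byte length form (with 2 reserved bytes) in
# explicit-VR transfer syntaxes
LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "OV", "SQ", "UC", "UR", "UT", "UN")

# string-valued VRs whose text is surfaced in snapshots and diffs
STRING_VRS <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT", "PN",
                "SH", "ST", "TM", "UC", "UI", "UR", "UT")
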