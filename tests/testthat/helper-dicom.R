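# Writes small synthetic DICOM series with pydicom (an independent writer)
# for the reader tests. Pixel value = 1100 + 10*k per slice k, plus a marker
# voxel of 3000 at (row 2, col 3) of slice 0; RescaleIntercept -1024.

write_dicom_fixture <- function(dir, n_slices = 5, dz = 2.5,
                                pixel_spacing = c(0.7, 0.9),
                                iop = c(1, 0, 0, 0, 1, 0),
                                gaps = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  zs <- if (is.null(gaps)) (seq_len(n_slices) - 1) * dz else cumsum(c(0, gaps))
  script <- sprintf('
import numpy as np, pydicom, os
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid
outdir = %s
zs = %s
iop = %s
series_uid = generate_uid()
for k, z in enumerate(zs):
    meta = FileMetaDataset()
    meta.MediaStorageSOPClassUID = pydicom.uid.CTImageStorage
    meta.MediaStorageSOPInstanceUID = generate_uid()
    meta.TransferSyntaxUID = ExplicitVRLittleEndian
    ds = Dataset()
    ds.file_meta = meta
    ds.SOPClassUID = meta.MediaStorageSOPClassUID
    ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID
    ds.SeriesInstanceUID = series_uid
    ds.Modality = "CT"
    ds.Rows, ds.Columns = 6, 8
    ds.PixelSpacing = [%s, %s]
    ds.ImagePositionPatient = [0.0, 0.0, float(z)]
    ds.ImageOrientationPatient = [float(v) for v in iop]
    ds.BitsAllocated = 16
    ds.BitsStored = 16
    ds.HighBit = 15
    ds.PixelRepresentation = 1
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    ds.RescaleIntercept = -1024.0
    ds.RescaleSlope = 1.0
    arr = np.full((6, 8), 1100 + 10 * k, dtype=np.int16)
    if k == 0:
        arr[2, 3] = 3000
    ds.PixelData = arr.tobytes()
    ds.is_little_endian = True
    ds.is_implicit_VR = False
    pydicom.dcmwrite(os.path.join(outdir, "slice%%03d.dcm" %% k), ds,
                     enforce_file_format=True)
', deparse(dir), sprintf("[%s]", paste(zs, collapse = ",")),
   sprintf("[%s]", paste(iop, collapse = ",")),
   pixel_spacing[1], pixel_spacing[2])
  res <- system2("python", args = "-", input = script,
                 stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(res, "status")) && attr(res, "status") != 0)
    stop("pydicom fixture writer failed: ", paste(res, collapse = "\n"))
  invisible(dir)
}
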