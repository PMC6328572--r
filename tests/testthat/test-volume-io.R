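test_that("volume and mask constructors enforce their invariants", {
  expect_error(coro_volume(array(0, c(4, 4)), c(1, 1, 1)), "3D")
  expect_error(coro_volume(array(0, c(4, 4, 1))), "at least 2")
  expect_error(coro_volume(array(0, c(4, 4, 4)), spacing = c(1, -1, 1)),
               "positive")
  v <- coro_volume(array(0, c(4, 4, 4)), spacing = c(0.5, 0.5, 1),
                   origin = c(-1, 0, 2))
  expect_error(coro_mask(array(TRUE, c(3, 3, 3)), grid = v), "shape")
  m <- coro_mask(array(FALSE, c(4, 4, 4)), grid = v)
  expect_identical(m$spacing, v$spacing)
  expect_equal(voxel_volume(v), 0.25)
})

test_that("physical/index maps are exact inverses and flag out-of-bounds", {
  v <- coro_volume(array(0, c(10, 12, 14)), spacing = c(0.3, 0.4, 0.5),
                   origin = c(5, -2, 1))
  expect_equal(physical_to_index(v, v$origin)$index, c(0, 0, 0))
  expect_equal(physical_to_index(v, v$origin + v$spacing)$index, c(1, 1, 1))
  set.seed(42)
  for (i in 1:100) {
    idx <- runif(3, 0, c(9, 11, 13))
    back <- physical_to_index(v, index_to_physical(v, idx))
    expect_true(back$in_bounds)
    expect_lt(max(abs(back$index - idx)), 1e-9)
  }
  expect_false(physical_to_index(v, v$origin - 1)$in_bounds)
})

test_that("NIfTI round trips preserve data and grid metadata", {
  set.seed(7)
  v <- coro_volume(array(rnorm(32^3) * 100 + 50, c(32, 32, 32)),
                   spacing = c(0.4, 0.4, 0.5), origin = c(3, -4, 10))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_identical(v2$data, v$data)
  expect_lt(max(abs(v2$spacing - v$spacing)), 1e-6)
  expect_lt(max(abs(v2$origin - v$origin)), 1e-6)

  m <- coro_mask(array(runif(16^3) > 0.5, c(16, 16, 16)),
                 spacing = c(1, 1, 1))
  fm <- tempfile(fileext = ".nii.gz")
  write_mask(m, fm)
  m2 <- read_mask(fm)
  expect_identical(m2$data, m$data)

  empty <- coro_mask(array(FALSE, c(8, 8, 8)), spacing = c(1, 1, 1))
  fe <- tempfile(fileext = ".nii.gz")
  write_mask(empty, fe)
  expect_equal(sum(read_mask(fe)$data), 0)
  full <- coro_mask(array(TRUE, c(16, 16, 16)), spacing = c(1, 1, 1))
  ff <- tempfile(fileext = ".nii.gz")
  write_mask(full, ff)
  expect_equal(sum(read_mask(ff)$data), 4096)
})

test_that("read_volume errors are explicit", {
  expect_error(read_volume(tempfile()), "no such file")
  bad <- tempfile(fileext = ".nii")
  writeLines("not a nifti", bad)
  expect_error(suppressWarnings(read_volume(bad)), "unreadable")
})

test_that("DICOM series are read with HU rescale, spacing and axis order", {
  gen <- "
import sys, os, pydicom, numpy as np
from pydicom.dataset import Dataset, FileDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid
out = sys.argv[1]
series = generate_uid()
for k in range(3):
    ds = FileDataset(None, Dataset(), file_meta=None, preamble=bytes(128))
    ds.file_meta = pydicom.dataset.FileMetaDataset()
    ds.file_meta.TransferSyntaxUID = ExplicitVRLittleEndian
    ds.file_meta.MediaStorageSOPClassUID = generate_uid()
    ds.file_meta.MediaStorageSOPInstanceUID = generate_uid()
    ds.SOPInstanceUID = ds.file_meta.MediaStorageSOPInstanceUID
    ds.SeriesInstanceUID = series if len(sys.argv) < 3 else generate_uid()
    ds.Rows = 4; ds.Columns = 5
    ds.PixelSpacing = [0.7, 0.6]
    ds.ImagePositionPatient = [0, 0, 2.0 * k]
    ds.ImageOrientationPatient = [1, 0, 0, 0, 1, 0]
    ds.RescaleSlope = 1; ds.RescaleIntercept = -1024
    ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15
    ds.PixelRepresentation = 0; ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = 'MONOCHROME2'
    arr = (np.arange(20, dtype=np.uint16).reshape(4, 5) + 1424 + k)
    ds.PixelData = arr.tobytes()
    ds.save_as(os.path.join(out, 's%d.dcm' % k), write_like_original=False)
print('ok')
"
  pyf <- tempfile(fileext = ".py")
  writeLines(gen, pyf)
  d <- tempfile()
  dir.create(d)
  out <- suppressWarnings(system2("python", c(pyf, d), stdout = TRUE,
                                  stderr = TRUE))
  expect_true(any(grepl("ok", out)))

  v <- read_volume(d)
  expect_equal(dim(v$data), c(5L, 4L, 3L))          # (cols, rows, slices)
  expect_equal(v$spacing, c(0.6, 0.7, 2.0))
  # stored value 1424 with intercept -1024 -> 400 HU at the first voxel
  expect_equal(v$data[1, 1, 1], 400)
  # column index varies fastest in the byte stream
  expect_equal(v$data[2, 1, 1], 401)
  expect_equal(v$data[1, 2, 1], 405)

  # a directory holding two different series is an ambiguity error
  d2 <- tempfile()
  dir.create(d2)
  out2 <- suppressWarnings(system2("python", c(pyf, d2, "multi"),
                                   stdout = TRUE, stderr = TRUE))
  expect_true(any(grepl("ok", out2)))
  expect_error(read_volume(d2), "series")
})
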