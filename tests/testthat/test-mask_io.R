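# mask_io: NIfTI round trips, validation, resampling.

test_that("write/read round trip is lossless for data, spacing, transform", {
  g <- block_grid(c(10, 12, 8), c(3, 4, 2), c(7, 9, 6), sp = 1)
  g$spacing <- c(1, 1, 3)
  g$transform[1:3, 1:3] <- diag(g$spacing)
  g$transform[1:3, 4] <- c(-12.5, 3.25, 7)
  for (ext in c(".nii", ".nii.gz")) {
    path <- withr::local_tempfile(fileext = ext)
    write_mask(g, path)
    back <- read_mask(path, label = "tumor")
    expect_identical(back$data, g$data)
    expect_identical(back$spacing, g$spacing)
    expect_equal(back$transform, g$transform, tolerance = 1e-6)
  }
})

test_that("an all-ones cube reads back with the right voxel count", {
  g <- volume_grid(array(1L, c(10, 10, 10)), c(1, 1, 1))
  path <- withr::local_tempfile(fileext = ".nii")
  write_mask(g, path)
  back <- read_mask(path)
  expect_equal(sum(back$data), 1000)
  expect_equal(back$spacing, c(1, 1, 1))
})

test_that("empty masks and exotic spacings survive the round trip", {
  g <- volume_grid(array(0L, c(5, 6, 7)), c(0.5, 0.5, 2.5))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(g, path)
  back <- read_mask(path)
  expect_equal(sum(back$data), 0)
  expect_equal(back$spacing, c(0.5, 0.5, 2.5))
  expect_identical(dim(back$data), c(5L, 6L, 7L))
})

test_that("read_mask rejects missing files, 4D volumes and bad spacing", {
  expect_error(read_mask(file.path(tempdir(), "nope.nii")),
               class = "tumorshape_io_error")

  # hand-build a 4D header by patching dim[0] and dim[4]
  g <- volume_grid(array(1L, c(4, 4, 4)), c(1, 1, 1))
  path <- withr::local_tempfile(fileext = ".nii")
  write_mask(g, path)
  raw <- readBin(path, "raw", file.size(path))
  raw[41:42] <- writeBin(4L, raw(), size = 2, endian = "little")  # dim[0] = 4
  raw[49:50] <- writeBin(2L, raw(), size = 2, endian = "little")  # dim[4] = 2
  bad <- withr::local_tempfile(fileext = ".nii")
  writeBin(raw, bad)
  expect_error(read_mask(bad), class = "tumorshape_io_error")
  expect_error(read_mask(bad), "3D")

  raw2 <- readBin(path, "raw", file.size(path))
  raw2[81:84] <- writeBin(-1, raw(), size = 4, endian = "little") # pixdim[1] < 0
  bad2 <- withr::local_tempfile(fileext = ".nii")
  writeBin(raw2, bad2)
  expect_error(read_mask(bad2), "pixdim", class = "tumorshape_io_error")
})

test_that("nibabel agrees with our writer and our reader handles its output", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  g <- block_grid(c(6, 7, 8), c(2, 3, 3), c(4, 5, 6), sp = 1)
  g$spacing <- c(0.8, 1, 1.25)
  g$transform[1:3, 1:3] <- diag(g$spacing)
  ours <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(g, ours)
  out <- system2("python", c("-c", shQuote(paste0(
    "import nibabel, numpy; img = nibabel.load('", ours, "'); ",
    "d = numpy.asarray(img.dataobj); ",
    "print(int(d.sum()), *d.shape, *numpy.round(img.header.get_zooms(), 6))"
  ))), stdout = TRUE)
  fields <- strsplit(trimws(out), " +")[[1]]
  expect_equal(as.integer(fields[1]), sum(g$data))
  expect_equal(as.integer(fields[2:4]), dim(g$data))
  expect_equal(as.numeric(fields[5:7]), g$spacing, tolerance = 1e-5)

  # nibabel-written NIfTI-1 (int16) and NIfTI-2 read back identically
  for (klass in c("Nifti1Image", "Nifti2Image")) {
    theirs <- withr::local_tempfile(fileext = ".nii")
    status <- system2("python", c("-c", shQuote(paste0(
      "import nibabel, numpy\n",
      "rng = numpy.random.default_rng(0)\n",
      "d = (rng.random((5, 6, 7)) < 0.5).astype(numpy.int16)\n",
      "aff = numpy.diag([1.5, 1.0, 2.0, 1.0])\n",
      "nibabel.", klass, "(d, aff).to_filename('", theirs, "')\n",
      "print(int(d.sum()))"
    ))), stdout = TRUE)
    back <- read_mask(theirs)
    expect_equal(sum(back$data), as.integer(trimws(status)))
    expect_equal(back$spacing, c(1.5, 1, 2))
  }
})

test_that("validate_pair enforces geometry identity and containment", {
  brain <- block_grid(c(20, 20, 20), c(1, 1, 1), c(20, 20, 20), label = "brain")
  tumor <- block_grid(c(20, 20, 20), c(8, 8, 8), c(12, 12, 12), label = "tumor")
  pair <- validate_pair(tumor, brain)
  expect_s3_class(pair, "segmentation_pair")

  shrunk <- tumor; shrunk$spacing <- c(0.9, 0.9, 0.9)
  expect_error(validate_pair(shrunk, brain), "spacing",
               class = "tumorshape_validation_error")
  small <- block_grid(c(19, 20, 20), c(8, 8, 8), c(12, 12, 12))
  expect_error(validate_pair(small, brain), "dimensions",
               class = "tumorshape_validation_error")
  moved <- tumor; moved$transform[1, 4] <- 5
  expect_error(validate_pair(moved, brain), "transform",
               class = "tumorshape_validation_error")
})

test_that("containment errors report the violating voxel count", {
  brain <- block_grid(c(10, 10, 10), c(1, 1, 1), c(10, 10, 5), label = "brain")
  tumor <- block_grid(c(10, 10, 10), c(4, 4, 4), c(5, 5, 6), label = "tumor")
  # tumor slab at z = 6 pokes out of the brain: 2 x 2 x ... voxels
  n_out <- sum(tumor$data != 0 & brain$data == 0)
  err <- tryCatch(validate_pair(tumor, brain), condition = identity)
  expect_s3_class(err, "tumorshape_validation_error")
  expect_equal(err$count, n_out)
  expect_match(conditionMessage(err), as.character(n_out))
})

test_that("identity resample preserves the lattice; refinement preserves volume", {
  g <- ball_grid(10, sp = 1)
  same <- resample_isotropic(g, 1)
  expect_equal(sum(same$data), sum(g$data))
  fine <- resample_isotropic(g, 0.5)
  v0 <- mask_volume(g); v1 <- mask_volume(fine)
  expect_rel_error(v1, v0, 0.02)
  # world bounding box is preserved within one target voxel
  expect_equal(fine$transform[1:3, 4] - 0.25, g$transform[1:3, 4] - 0.5,
               tolerance = 0.51)
})

test_that("resampling an anisotropic grid onto isotropic keeps world extent", {
  a <- array(0L, c(12, 12, 6)); a[4:9, 4:9, 2:5] <- 1L
  g <- volume_grid(a, c(1, 1, 2))
  iso <- resample_isotropic(g, 1)
  expect_equal(iso$spacing, c(1, 1, 1))
  expect_equal(dim(iso$data), c(12L, 12L, 12L))
  expect_rel_error(mask_volume(iso), mask_volume(g), 0.05)
  empty <- resample_isotropic(volume_grid(array(0L, c(4, 4, 4)), c(2, 2, 2)), 1)
  expect_equal(sum(empty$data), 0)
})

test_that("resample_isotropic rejects nonpositive spacing", {
  g <- ball_grid(5)
  expect_error(resample_isotropic(g, 0), class = "tumorshape_validation_error")
  expect_error(resample_isotropic(g, -1), class = "tumorshape_validation_error")
})
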