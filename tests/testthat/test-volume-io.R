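test_that("RAW volumes round-trip bit-identically in 8 and 16 bit", {
  td <- withr::local_tempdir()
  v8 <- voxel_volume(array(0:7, c(2, 2, 2)), volume_meta(2, 2, 2, 110, 8))
  p8 <- file.path(td, "v8.raw")
  write_raw_volume(v8, p8)
  expect_identical(read_raw_volume(p8)$data, v8$data)
  # file bytes are exactly 0..7 in x-fastest order
  expect_identical(as.integer(readBin(p8, "raw", 8)), 0:7)

  for (bo in c("little", "big")) {
    meta <- volume_meta(4, 4, 4, 110, 16, bo)
    v <- voxel_volume(array(c(0L, 65535L, sample.int(65536L, 62) - 1L),
                            c(4, 4, 4)), meta)
    p <- file.path(td, paste0("v16", bo, ".raw"))
    write_raw_volume(v, p)
    expect_identical(read_raw_volume(p)$data, v$data)
  }
})

test_that("a 16-bit fixture written by an independent byte-level writer is read at the right index", {
  td <- withr::local_tempdir()
  p <- file.path(td, "ind.raw")
  # little-endian 4x4x4, all zero except voxel (x=3, y=2, z=4) = 65535;
  # linear offset (0-based): (3-1) + 4*(2-1) + 16*(4-1) = 54
  bytes <- rep(as.raw(0), 128)
  bytes[2 * 54 + 1:2] <- as.raw(c(0xff, 0xff))
  writeBin(bytes, p)
  v <- read_raw_volume(p, volume_meta(4, 4, 4, 110, 16, "little"))
  expect_equal(v$data[3, 2, 4], 65535)
  expect_equal(sum(v$data), 65535)
})

test_that("RAW reading rejects size mismatches and bad bit depths", {
  td <- withr::local_tempdir()
  p <- file.path(td, "bad.raw")
  writeBin(as.raw(1:10), p)
  expect_error(read_raw_volume(p, volume_meta(2, 2, 2, 110, 16)),
               "size mismatch")
  expect_error(volume_meta(2, 2, 2, 110, 12), "bit_depth")
})

test_that("slice stacks round-trip losslessly, 16-bit included", {
  td <- withr::local_tempdir()
  meta <- volume_meta(6, 5, 5, 110, 16)
  v <- voxel_volume(array(sample.int(65536L, 150) - 1L, c(6, 5, 5)), meta)
  d1 <- file.path(td, "s16")
  files <- volume_to_slices(v, d1)
  expect_length(files, 5)
  expect_match(basename(files[1]), "^slice_0000")
  expect_identical(read_slice_stack(d1)$data, v$data)  # no 8-bit downcast
  expect_error(volume_to_slices(v, d1), "exist")       # overwrite guard

  v8 <- voxel_volume(array(sample.int(256L, 150) - 1L, c(6, 5, 5)),
                     volume_meta(6, 5, 5, 110, 8))
  d2 <- file.path(td, "s8")
  volume_to_slices(v8, d2, format = "png")
  expect_identical(read_slice_stack(d2)$data, v8$data)
})

test_that("point clouds use voxel centres and scale with voxel size", {
  td <- withr::local_tempdir()
  m <- array(FALSE, c(3, 3, 3)); m[1, 1, 1] <- TRUE
  bv <- binary_volume(m, volume_meta(3, 3, 3, 100))
  p <- file.path(td, "one.obj")
  write_point_cloud(bv, p, "obj")
  lines <- readLines(p)
  expect_length(lines, 1)
  expect_equal(read_point_cloud(p)[1, ], c(x = 50, y = 50, z = 50))

  m2 <- array(FALSE, c(4, 4, 4)); m2[sample(64, 10)] <- TRUE
  for (vs in c(100, 200)) {
    bv2 <- binary_volume(m2, volume_meta(4, 4, 4, vs))
    p2 <- file.path(td, paste0("ten", vs, ".xyz"))
    write_point_cloud(bv2, p2, "xyz")
    expect_length(readLines(p2), 10)
  }
  a <- read_point_cloud(file.path(td, "ten100.xyz"))
  b <- read_point_cloud(file.path(td, "ten200.xyz"))
  expect_equal(b, a * 2)   # physical coordinates scale linearly

  empty <- binary_volume(array(FALSE, c(2, 2, 2)), volume_meta(2, 2, 2, 100))
  expect_error(write_point_cloud(empty, file.path(td, "e.xyz")), "empty")
})
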