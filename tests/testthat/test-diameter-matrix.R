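test_that("read/write round-trips a trivial matrix exactly", {
  dm <- diameter_matrix(matrix(5, 3, 3), position_spacing_mm = 1,
                        frame_interval_s = 1)
  expect_equal(dm$intestine_length_mm, 3)
  path <- file.path(tempdir(), "trivial.tsv")
  write_diameter_matrix(dm, path)
  back <- read_diameter_matrix(path)
  expect_identical(back$values, dm$values)
  expect_identical(back[-1], dm[-1])
})

test_that("invalid matrices and sidecars are rejected", {
  expect_error(diameter_matrix(matrix(-1, 3, 3), 1, 1), "negative")
  expect_error(diameter_matrix(matrix(NaN, 3, 3), 1, 1), "finite")
  expect_error(diameter_matrix(matrix(5, 3, 3), 1, 0), "frame_interval")
  expect_error(diameter_matrix(matrix(5, 3, 3), 1, 1,
                               intestine_length_mm = 10), "disagrees")
  path <- file.path(tempdir(), "bad.tsv")
  write.table(matrix(c(5, 5, -2, 5), 2, 2), path, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  writeLines(c("position_spacing_mm\t1", "frame_interval_s\t1",
               "t0_offset_s\t0", "intestine_length_mm\t2",
               "preparation_id\tx", "treatment\tempty"),
             paste0(path, ".meta"))
  expect_error(read_diameter_matrix(path), "negative")
  writeLines(c("position_spacing_mm\t1"), paste0(path, ".meta"))
  expect_error(read_diameter_matrix(path), "missing keys")
  writeLines(c("position_spacing_mm\t1", "position_spacing_mm\t2",
               "frame_interval_s\t1", "t0_offset_s\t0",
               "intestine_length_mm\t2", "preparation_id\tx",
               "treatment\tempty"), paste0(path, ".meta"))
  expect_error(read_diameter_matrix(path), "contradictory|duplicated")
})

test_that("a generated scenario round-trips through disk to 1e-9", {
  p <- default_params("cellulose")
  p$horizon_s <- 600
  scen <- generate_scenario(p, 1, seed = 3, lengths_mm = 55)
  dm <- render_diameter_matrix(scen, 1, p$frame_rate_detect, 0, 600)
  path <- file.path(tempdir(), "scen.tsv")
  write_diameter_matrix(dm, path)
  back <- read_diameter_matrix(path)
  expect_lt(max(abs(back$values - dm$values)), 1e-9)
  expect_identical(back$preparation_id, dm$preparation_id)
})

test_that("frame subsampling follows the stated arithmetic", {
  dm <- diameter_matrix(matrix(runif(10 * 35, 4, 6), 10, 35), 1, 1 / 3.5)
  coarse <- subsample_frames(dm, 10)
  expect_equal(ncol(coarse$values), 4)       # frames 1, 11, 21, 31
  expect_equal(1 / coarse$frame_interval_s, 0.35)
  expect_identical(subsample_frames(dm, 1), dm)
  mid <- subsample_frames(dm, 3)
  expect_equal(mid$frame_interval_s, 3 / 3.5)
  expect_error(subsample_frames(dm, 0), "positive integer")
})

test_that("subsampling by a*b equals subsampling by a then b", {
  set.seed(5)
  dm <- diameter_matrix(matrix(runif(4 * 120, 3, 7), 4, 120), 2, 0.5)
  for (ab in list(c(2, 3), c(3, 4), c(5, 2))) {
    lhs <- subsample_frames(dm, ab[1] * ab[2])
    rhs <- subsample_frames(subsample_frames(dm, ab[1]), ab[2])
    expect_identical(lhs, rhs)
  }
})

test_that("segment partition places boundaries at cumulative fractions", {
  dm <- diameter_matrix(matrix(5, 400, 2), 0.25, 1)
  part <- partition_segments(dm)
  expect_equal(part$boundaries_mm, c(0, 39, 62, 85, 100))
  dm70 <- diameter_matrix(matrix(5, 280, 2), 0.25, 1)
  part70 <- partition_segments(dm70)
  expect_equal(part70$boundaries_mm[2], 27.3)
  expect_equal(part70$segment_length_mm[1], 27.3)
  expect_error(partition_segments(dm, c(1, 0, 0, 0)), "positive")
  expect_error(partition_segments(dm, c(0.4, 0.3, 0.2, 0.2)), "sum to 1")
})

test_that("segment assignment is total and exclusive", {
  set.seed(7)
  for (n in c(37, 100, 283)) {
    dm <- diameter_matrix(matrix(5, n, 2), 0.31, 1)
    part <- partition_segments(dm)
    expect_length(part$segment_of, n)
    expect_true(all(part$segment_of %in% 1:4))
    counts <- tabulate(part$segment_of, 4)
    expect_equal(sum(counts), n)             # every position exactly once
    expect_true(all(diff(part$segment_of) >= 0))  # contiguous, ordered
  }
})

test_that("ST map rendering is deterministic and rejects bad input", {
  skip_if_not_installed("png")
  dm <- make_dip_matrix(n_pos = 40, n_frames = 60,
                        dips = list(list(t0 = 10, dur = 15, x0 = 5,
                                         v = 0.2, depth = 0.4)))
  f1 <- file.path(tempdir(), "st1.png"); f2 <- file.path(tempdir(), "st2.png")
  render_st_map(dm, f1); render_st_map(dm, f2)
  expect_identical(png::readPNG(f1), png::readPNG(f2))
  expect_error(render_st_map(dm, file.path(tempdir(), "nodir", "x.png")),
               "directory")
  expect_error(diameter_matrix(matrix(numeric(0), 0, 0), 1, 1), "frames")
})
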