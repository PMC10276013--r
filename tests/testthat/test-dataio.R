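# Image/mask loading, Lanczos rescaling, binarization, splits, manifests.

write_test_pair <- function(dir, id, h, w, mask_values = c(0, 1)) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  img <- array(runif(h * w * 3), c(h, w, 3))
  msk <- matrix(sample(mask_values, h * w, replace = TRUE), h, w)
  png::writePNG(img, file.path(dir, "images", paste0(id, ".png")))
  png::writePNG(msk, file.path(dir, "masks", paste0(id, ".png")))
  list(image = img, mask = msk)
}

test_that("load_pair rescales to target size and binarizes the mask", {
  dir <- withr::local_tempdir()
  set.seed(1)
  write_test_pair(dir, "a", 288, 384)   # CVC-ClinicDB geometry (rows x cols)
  sp <- load_pair(file.path(dir, "images", "a.png"),
                  file.path(dir, "masks", "a.png"), target_size = 352)
  expect_equal(dim(sp$image), c(352, 352, 3))
  expect_equal(dim(sp$mask), c(352, 352))
  expect_true(all(sp$mask %in% c(0, 1)))
  expect_true(all(sp$image >= 0 & sp$image <= 1))
  expect_equal(sp$id, "a")

  # determinism: loading twice is bit-identical
  sp2 <- load_pair(file.path(dir, "images", "a.png"),
                   file.path(dir, "masks", "a.png"), target_size = 352)
  expect_identical(sp$image, sp2$image)
  expect_identical(sp$mask, sp2$mask)

  expect_error(load_pair(file.path(dir, "nope.png"),
                         file.path(dir, "masks", "a.png"), 64), "nope")
})

test_that("a {0, 255}-valued mask loads as exactly {0, 1}", {
  dir <- withr::local_tempdir()
  set.seed(2)
  write_test_pair(dir, "b", 64, 64)
  sp <- load_pair(file.path(dir, "images", "b.png"),
                  file.path(dir, "masks", "b.png"), target_size = 64)
  expect_true(all(sp$mask %in% c(0, 1)))
  # nearest-neighbour at identical size: binarization is exact
  orig <- png::readPNG(file.path(dir, "masks", "b.png"))
  expect_equal(sp$mask, (orig > 127 / 255) * 1, ignore_attr = TRUE)
})

test_that("Lanczos resampling preserves constants and reduces as expected", {
  const <- matrix(0.37, 30, 45)
  out <- resize_lanczos(const, 20, 20)
  expect_equal(out, matrix(0.37, 20, 20), tolerance = 1e-12)
  # nearest-neighbour keeps the value set
  m <- matrix(sample(c(0, 1), 33 * 21, replace = TRUE), 33, 21)
  out_n <- resize_nearest(m, 16, 16)
  expect_true(all(out_n %in% c(0, 1)))
})

test_that("splits are exact, disjoint, exhaustive, and seed-reproducible", {
  for (n in c(10, 612, 1000)) {
    ids <- sprintf("id%04d", seq_len(n))
    sp <- split_dataset(ids, split_spec(seed = 7))
    expect_equal(lengths(sp)[["train"]], floor(0.8 * n))
    expect_equal(lengths(sp)[["val"]], floor(0.1 * n))
    expect_equal(lengths(sp)[["test"]], n - floor(0.8 * n) - floor(0.1 * n))
    expect_setequal(unlist(sp), ids)
    expect_equal(anyDuplicated(unlist(sp)), 0L)
    expect_identical(sp, split_dataset(ids, split_spec(seed = 7)))
    expect_false(identical(sp$train, split_dataset(ids, split_spec(seed = 8))$train))
  }
  expect_equal(lengths(split_dataset(sprintf("x%d", 1:612), split_spec(seed = 1))),
               c(train = 489L, val = 61L, test = 62L))
})

test_that("split partition property holds across sizes (property test)", {
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(3:80, 1)
    ids <- sprintf("s%03d", seq_len(n))
    sp <- split_dataset(ids, split_spec(seed = rep))
    expect_setequal(unlist(sp), ids)
    expect_equal(length(unlist(sp)), n)
  }
  expect_error(split_dataset(c("a", "b"), split_spec()), "at least 3")
  expect_error(split_dataset(c("a", "a", "b"), split_spec()), "unique")
  expect_error(split_spec(0.5, 0.2, 0.2), "sum to 1")
})

test_that("split manifests round-trip as plain text", {
  dir <- withr::local_tempdir()
  sp <- split_dataset(sprintf("im%02d", 1:20), split_spec(seed = 3))
  write_split(sp, dir)
  expect_identical(read_split(dir), sp)
  expect_true(all(file.exists(file.path(dir, c("train.txt", "val.txt",
                                               "test.txt")))))
})

test_that("mask save/load is idempotent and thresholding matches", {
  dir <- withr::local_tempdir()
  set.seed(9)
  m <- random_mask(24, 24)
  p1 <- file.path(dir, "m.png")
  save_mask(m, p1)
  expect_equal(png::readPNG(p1), m, ignore_attr = TRUE)
  # save -> load -> save -> load fixed point
  save_mask(png::readPNG(p1), file.path(dir, "m2.png"))
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(file.path(dir, "m2.png"), "raw",
                           file.size(file.path(dir, "m2.png"))))

  # probability map with threshold == pre-thresholded mask, byte for byte
  prob <- matrix(runif(24 * 24), 24, 24)
  pa <- file.path(dir, "a.png"); pb <- file.path(dir, "b.png")
  save_mask(prob, pa, threshold = 0.5)
  save_mask((prob >= 0.5) * 1, pb)
  expect_identical(readBin(pa, "raw", file.size(pa)),
                   readBin(pb, "raw", file.size(pb)))
  expect_error(save_mask(matrix(1.2, 2, 2), file.path(dir, "x.png")), "0, 1")
})

test_that("list_pairs matches images to masks by stem", {
  dir <- withr::local_tempdir()
  set.seed(4)
  write_test_pair(dir, "u", 16, 16)
  write_test_pair(dir, "v", 16, 16)
  png::writePNG(matrix(runif(16), 4, 4), file.path(dir, "images", "orphan.png"))
  expect_warning(pairs <- list_pairs(dir), "orphan|matching")
  expect_equal(pairs$id, c("u", "v"))
  expect_true(all(file.exists(pairs$image)))
  expect_true(all(file.exists(pairs$mask)))
})
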