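# Dataset loaders (folder trees, MATLAB containers) and the phantom generator.

test_that("folder trees load deterministically with one record per image", {
  root <- file.path(tempdir(), "tree-fixture")
  unlink(root, recursive = TRUE)
  ds <- generate_phantoms(phantom_config(n_per_class = 3, n_classes = 2,
                                         image_size = 32, seed = 3),
                          out_dir = root)
  idx <- load_folder_dataset(root)
  expect_length(idx$records, 6)
  expect_length(idx$class_names, 2)
  expect_equal(sort(unique(dataset_labels(idx))), 0:1)
  # repeated loads give identical ordering
  expect_identical(idx, load_folder_dataset(root))
  # class names come back in lexicographic order, so the lesion class is 0
  expect_equal(idx$class_names, c("lesion_anterior", "no_lesion"))
  # decoded pixels match the in-memory stack (8-bit quantization aside);
  # record 1 on disk is the first lesion image, record 4 of the generator
  img_mem <- dataset_images(ds, which(dataset_labels(ds) == 1)[1])[[1]]
  img_disk <- dataset_images(idx, 1)[[1]]
  expect_lt(max(abs(img_mem - img_disk)), 256 / 255)
  expect_error(load_folder_dataset(file.path(root, "missing")), "directory")
})

test_that("undecodable files are skipped with a warning, the rest intact", {
  root <- file.path(tempdir(), "tree-corrupt")
  unlink(root, recursive = TRUE)
  generate_phantoms(phantom_config(n_per_class = 2, n_classes = 2,
                                   image_size = 32, seed = 5), out_dir = root)
  writeLines("not a png", file.path(root, "no_lesion", "0000.png"))
  expect_warning(idx <- load_folder_dataset(root), "skipping undecodable")
  expect_length(idx$records, 4)
})

test_that("legacy MATLAB containers round-trip slice records bit-exactly", {
  dir <- file.path(tempdir(), "mat-legacy")
  unlink(dir, recursive = TRUE); dir.create(dir)
  set.seed(13)
  img <- matrix(round(runif(512 * 512, 0, 255)), 512, 512)
  write_mat5(list(cjdata = list(label = matrix(3, 1, 1), image = img)),
             file.path(dir, "s1.mat"))
  write_mat5(list(cjdata = list(label = matrix(1, 1, 1),
                                image = matrix(1:16, 4, 4))),
             file.path(dir, "s2.mat"))
  idx <- load_mat_dataset(dir)
  expect_length(idx$records, 2)
  # stored labels {1, 3} remap to dense 0-based ids; files sort s1 < s2
  expect_equal(dataset_labels(idx), c(1L, 0L))
  expect_identical(dataset_images(idx, 1)[[1]], img)
  # a file without the expected fields reports its name
  write_mat5(list(other = matrix(1, 2, 2)), file.path(dir, "bad.mat"))
  expect_error(load_mat_dataset(dir), "bad.mat")
})

test_that("HDF5-based and legacy containers yield identical indices", {
  skip_if_not_installed("rhdf5")
  d1 <- file.path(tempdir(), "mat-v5"); d2 <- file.path(tempdir(), "mat-h5")
  unlink(c(d1, d2), recursive = TRUE); dir.create(d1); dir.create(d2)
  set.seed(21)
  for (i in 1:3) {
    img <- matrix(round(runif(64 * 48, 0, 255)), 64, 48)
    lab <- matrix((i - 1) %% 3 + 1, 1, 1)
    write_mat5(list(cjdata = list(label = lab, image = img)),
               file.path(d1, sprintf("s%d.mat", i)))
    f <- file.path(d2, sprintf("s%d.mat", i))
    rhdf5::h5createFile(f)
    rhdf5::h5createGroup(f, "cjdata")
    # the HDF5 container dialect stores arrays with reversed dimensions
    rhdf5::h5write(t(img), f, "cjdata/image")
    rhdf5::h5write(lab, f, "cjdata/label")
    rhdf5::h5closeAll()
  }
  i1 <- load_mat_dataset(d1)
  i2 <- load_mat_dataset(d2)
  expect_equal(dataset_labels(i1), dataset_labels(i2))
  for (i in 1:3) {
    expect_equal(dataset_images(i1, i)[[1]], dataset_images(i2, i)[[1]])
  }
})

test_that("phantom stacks are seeded, balanced and carry class signal", {
  cfg <- phantom_config(n_per_class = 12, n_classes = 4, image_size = 48,
                        seed = 77)
  a <- generate_phantoms(cfg)
  b <- generate_phantoms(cfg)
  expect_identical(dataset_images(a), dataset_images(b))
  expect_equal(as.integer(table(dataset_labels(a))), rep(12L, 4))
  expect_false(identical(
    dataset_images(a, 1),
    dataset_images(generate_phantoms(phantom_config(12, 4, 48, seed = 78)), 1)))

  # linear probe on lesion-region mean intensities beats chance, confirming
  # learnable class structure
  ds <- generate_phantoms(phantom_config(n_per_class = 40, n_classes = 4,
                                         image_size = 48, seed = 101))
  region_feats <- function(img) {
    s <- nrow(img)
    box <- function(cx, cy, r) {
      rows <- max(1, round((cy - r) * s)):min(s, round((cy + r) * s))
      cols <- max(1, round((cx - r) * s)):min(s, round((cx + r) * s))
      mean(img[rows, cols])
    }
    c(box(0.35, 0.35, 0.10), box(0.50, 0.50, 0.14), box(0.63, 0.63, 0.08))
  }
  X <- t(vapply(dataset_images(ds), region_feats, numeric(3)))
  y <- dataset_labels(ds)
  sp <- make_split(y, split_spec("ratio", 0.7, 0.15, 0.15, seed = 5))
  # nearest-centroid linear probe
  cents <- sapply(0:3, function(k) colMeans(X[sp$train, ][y[sp$train] == k, ]))
  pred <- apply(X[sp$test, ], 1, function(v)
    which.min(colSums((cents - v)^2)) - 1L)
  expect_gt(mean(pred == y[sp$test]), 0.5)    # chance is 0.25
})
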