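# Fixture generators: determinism, constructive bounds on foreground
# fractions and component counts, layer separation, and lossless round trips.

test_that("generation is bit-reproducible from the seed", {
  spec <- fixture_spec("brain_like", n_images = 3, seed = 7)
  a <- generate_brain_like(spec)
  b <- generate_brain_like(spec)
  expect_identical(a, b)

  specs <- fixture_spec("smear_like", n_images = 3, seed = 7)
  expect_identical(generate_smear_like(specs), generate_smear_like(specs))
})

test_that("brain-like masks are binary, paired, and obey the small-target
           regime", {
  spec <- fixture_spec("brain_like", n_images = 12, height = 128, width = 128,
                       foreground_fraction_range = c(0.001, 0.01),
                       small_target_probability = 1, seed = 3)
  samples <- generate_brain_like(spec)
  for (s in samples) {
    expect_true(all(s$mask %in% c(0, 1)))
    expect_identical(dim(s$image)[1:2], dim(s$mask))
    expect_true(all(s$image >= 0 & s$image <= 1))
    frac <- mean(s$mask)
    # constructive bound up to rasterisation error on small ellipses
    expect_gte(frac, 0.0003)
    expect_lte(frac, 0.015)
  }
})

test_that("the sampled foreground fraction follows its uniform law", {
  spec <- fixture_spec("brain_like", n_images = 200, height = 96, width = 96,
                       foreground_fraction_range = c(0.02, 0.2),
                       small_target_probability = 0, noise_sigma = 0, seed = 5)
  samples <- generate_brain_like(spec)
  fracs <- vapply(samples, function(s) mean(s$mask), numeric(1))
  mid <- mean(c(0.02, 0.2))
  expect_lt(abs(mean(fracs) - mid) / mid, 0.2)
})

test_that("smear-like images respect cell-count bounds and adhesion produces a
           single touching component", {
  spec <- fixture_spec("smear_like", n_images = 10, height = 96, width = 96,
                       n_cells_range = c(1, 10), adhesion_probability = 0.5,
                       seed = 11)
  for (s in generate_smear_like(spec)) {
    expect_true(all(s$mask %in% c(0, 1)))
    expect_equal(dim(s$image)[3], 3L)
    ncomp <- count_components(s$mask)
    expect_gte(ncomp, 1L)
    expect_lte(ncomp, 10L)
  }

  # forced adhesion with exactly two cells: one merged component
  spec2 <- fixture_spec("smear_like", n_images = 6, height = 96, width = 96,
                        n_cells_range = c(2, 2), adhesion_probability = 1,
                        seed = 13)
  for (s in generate_smear_like(spec2))
    expect_equal(count_components(s$mask), 1L)
})

test_that("distractor disks never enter the mask", {
  spec <- fixture_spec("smear_like", n_images = 8, seed = 17)
  for (s in generate_smear_like(spec)) {
    distr <- attr(s, "distractor_mask")
    expect_false(is.null(distr))
    expect_true(sum(distr) > 0)
    expect_equal(sum(s$mask * distr), 0)
  }
})

test_that("png_pairs fixtures round-trip bit-exactly through disk", {
  spec <- fixture_spec("brain_like", n_images = 5, seed = 23)
  samples <- generate_brain_like(spec)
  dir <- tempfile("fix")
  manifest <- write_fixture_set(samples, dir, "png_pairs", kind = "brain_like",
                                seed = 23)
  expect_equal(length(list.files(dir, pattern = "\\.png$")), 10L)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  loaded <- load_dataset(dir, "png_pairs")
  expect_length(loaded, 5L)
  for (i in 1:5) {
    expect_identical(loaded[[i]]$mask, samples[[i]]$mask)
    quantised <- round(samples[[i]]$image * 255) / 255
    expect_equal(loaded[[i]]$image, quantised, tolerance = 1e-12)
  }
})

test_that("nifti_stack writes a volume whose slices reload exactly", {
  spec <- fixture_spec("brain_like", n_images = 4, height = 64, width = 64,
                       seed = 29)
  samples <- generate_brain_like(spec)
  dir <- tempfile("nii")
  write_fixture_set(samples, dir, "nifti_stack", kind = "brain_like", seed = 29)
  vol <- as.array(RNifti::readNifti(file.path(dir, "image.nii")))
  expect_equal(dim(vol), c(64L, 64L, 4L))
  loaded <- load_dataset(dir, "nifti_volume")
  expect_length(loaded, 4L)
  for (i in 1:4) {
    expect_identical(loaded[[i]]$mask, samples[[i]]$mask)
    # the loader min-max normalises each slice; undo it for the comparison
    sl <- samples[[i]]$image[, , 1]
    rg <- range(sl)
    expect_equal(loaded[[i]]$image[, , 1], (sl - rg[1]) / diff(rg),
                 tolerance = 1e-12)
  }
})
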