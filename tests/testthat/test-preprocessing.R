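const_slice <- function(value, h = 20, w = 30) {
  octcsc:::new_slice_image(array(as.integer(value), c(h, w, 3)), 0L, FALSE)
}

test_that("crop extracts an untouched sub-grid and validates its window", {
  sp <- tiny_sp(noise_sd = 0)
  s <- render_slice("normal", FALSE, sp, seed = 1)
  p <- preprocess_params(crop_height = 30, crop_width = 50,
                         crop_origin = c(10, 20))
  cr <- crop_slice(s, p)
  expect_identical(dim(cr$pixels), c(30L, 50L, 3L))
  expect_identical(cr$pixels, s$pixels[10:39, 20:69, , drop = FALSE])
  expect_identical(cr$slice_index, s$slice_index)
  expect_identical(cr$is_lesion_cut, s$is_lesion_cut)

  ident <- crop_slice(s, preprocess_params(crop_height = 64,
                                           crop_width = 128))
  expect_identical(ident$pixels, s$pixels)

  expect_error(crop_slice(s, preprocess_params(crop_height = 100,
                                               crop_width = 10)), "height")
  expect_error(crop_slice(s, preprocess_params(crop_height = 10,
                                               crop_width = 500)), "width")

  cc <- crop_slice(const_slice(42), preprocess_params(crop_height = 10,
                                                      crop_width = 10))
  expect_true(all(cc$pixels == 42))
})

test_that("area-average downsampling has exact block semantics", {
  # pixel checkerboard (0/100): every 2x2 averaging block holds two of
  # each color, so 2:1 downsampling gives uniform mid-gray
  h <- 16; w <- 24
  board <- outer(seq_len(h), seq_len(w), "+") %% 2
  px <- array(as.integer(board * 100), c(h, w, 3))
  s <- octcsc:::new_slice_image(px, 0L, FALSE)
  dn <- downsample_slice(s, preprocess_params(target_height = 8,
                                              target_width = 12))
  expect_true(all(abs(dn$pixels - 50) < 1e-9))

  dc <- downsample_slice(const_slice(77, 20, 30),
                         preprocess_params(target_height = 7,
                                           target_width = 11))
  expect_true(all(abs(dc$pixels - 77) < 1e-9))   # mass preservation

  expect_error(downsample_slice(const_slice(1, 5, 5),
                                preprocess_params(target_height = 10,
                                                  target_width = 10)),
               "upsampling")
})

test_that("preprocessing presets produce the declared network input size", {
  sp <- tiny_sp(noise_sd = 5)
  s <- render_slice("acute", TRUE, sp, seed = 2)
  out <- downsample_slice(crop_slice(s, tiny_pp()), tiny_pp())
  expect_identical(dim(out$pixels), c(18L, 26L, 3L))
})

test_that("augmentation obeys its forced and neutral configurations", {
  sp <- tiny_sp(noise_sd = 0)
  s <- render_slice("chronic", TRUE, sp, seed = 4)
  # forced flip only -> exact mirror image
  fl <- with(list(), {set.seed(1); augment_slice(s, augment_params(
    hflip_probability = 1, brightness_range = c(1, 1),
    max_rotation_deg = 0))})
  expect_identical(fl$pixels, s$pixels[, 128:1, , drop = FALSE])
  # brightness 0.7 on a constant-100 image -> constant 70
  set.seed(2)
  br <- augment_slice(const_slice(100), augment_params(
    hflip_probability = 0, brightness_range = c(0.7, 0.7),
    max_rotation_deg = 0))
  expect_true(all(abs(br$pixels - 70) < 1e-9))
  # all-neutral parameters -> identity
  set.seed(3)
  id <- augment_slice(s, augment_params(hflip_probability = 0,
                                        brightness_range = c(1, 1),
                                        max_rotation_deg = 0))
  expect_identical(id$pixels, s$pixels)
  # rotation keeps dimensions and fills corners within range
  set.seed(4)
  ro <- augment_slice(s, augment_params(hflip_probability = 0,
                                        brightness_range = c(1, 1),
                                        max_rotation_deg = 15))
  expect_identical(dim(ro$pixels), dim(s$pixels) + 0L)
  expect_true(all(ro$pixels >= 0 & ro$pixels <= 255))
})

test_that("volume preprocessing is deterministic on the evaluation path", {
  cs <- tiny_cases(2)[[3]]
  v1 <- preprocess_volume(cs, tiny_pp(), training = FALSE)
  v2 <- preprocess_volume(cs, tiny_pp(), training = FALSE)
  expect_identical(v1, v2)
  expect_length(v1, 25)
  for (s in v1[c(1, 13, 25)])
    expect_identical(dim(s$pixels), c(18L, 26L, 3L))
  # training with neutral augmentation equals the evaluation path
  neutral <- augment_params(hflip_probability = 0,
                            brightness_range = c(1, 1), max_rotation_deg = 0)
  v3 <- preprocess_volume(cs, tiny_pp(), neutral, training = TRUE, seed = 1)
  expect_equal(v3, v1)
})

test_that("augment parameter validation rejects bad configurations", {
  expect_error(augment_params(hflip_probability = 1.5), "hflip")
  expect_error(augment_params(brightness_range = c(1.3, 0.7)), "brightness")
  expect_error(augment_params(max_rotation_deg = -1), "rotation")
})
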