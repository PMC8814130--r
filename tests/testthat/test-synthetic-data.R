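test_that("rendering is deterministic and respects the lesion contract", {
  sp <- tiny_sp()
  s1 <- render_slice("acute", TRUE, sp, seed = 7)
  s2 <- render_slice("acute", TRUE, sp, seed = 7)
  expect_identical(s1$pixels, s2$pixels)
  expect_true(s1$is_lesion_cut)
  expect_identical(dim(s1$pixels), c(sp$image_height, sp$image_width, 3L))
  expect_true(all(s1$pixels >= 0 & s1$pixels <= 255))
  expect_type(s1$pixels, "integer")

  n <- render_slice("normal", FALSE, sp, seed = 0)
  expect_false(n$is_lesion_cut)
  expect_error(render_slice("fuzzy", FALSE, sp), "unknown class label")
  expect_error(render_slice("normal", TRUE, sp), "lesion")
})

test_that("the acute fluid dome is hypo-intense relative to normal tissue", {
  sp <- tiny_sp(noise_sd = 0)
  reg <- acute_dome_region(sp)
  ac <- render_slice("acute", TRUE, sp, seed = 0)
  no <- render_slice("normal", FALSE, sp, seed = 0)
  m_ac <- mean(ac$pixels[reg$rows, reg$cols, 1])
  m_no <- mean(no$pixels[reg$rows, reg$cols, 1])
  expect_lt(m_ac, m_no)
  expect_gt(m_no - m_ac, 10)    # clear class-signal margin, gray levels
  # chronic phenotype differs from both in the outer-band region
  ch <- render_slice("chronic", TRUE, sp, seed = 0)
  expect_false(identical(ch$pixels, no$pixels))
  expect_false(identical(ch$pixels, ac$pixels))
})

test_that("non-lesion slices carry no lesion term", {
  sp <- tiny_sp(noise_sd = 0)
  a <- render_slice("acute", FALSE, sp, seed = 3)
  c <- render_slice("chronic", FALSE, sp, seed = 3)
  n <- render_slice("normal", FALSE, sp, seed = 3)
  expect_identical(a$pixels, n$pixels)
  expect_identical(c$pixels, n$pixels)
})

test_that("lesion-cut masks are contiguous central runs of the right length", {
  sp <- tiny_sp()
  expect_identical(assign_lesion_cuts("normal", sp), rep(FALSE, 25))
  full <- synth_params(image_height = 64, image_width = 128,
                       lesion_slice_range = c(25, 25))
  expect_identical(assign_lesion_cuts("acute", full, seed = 1),
                   rep(TRUE, 25))
  set.seed(99)
  lens <- replicate(1000, {
    m <- assign_lesion_cuts("chronic", sp)
    r <- which(m)
    expect_identical(r, r[1]:(r[1] + length(r) - 1))   # contiguity
    length(r)
  })
  expect_true(all(lens >= 5 & lens <= 15))
  expect_lt(abs(mean(lens) - 10), 0.5)   # uniform on 5..15 has mean 10
})

test_that("generated cases satisfy the volume invariants", {
  sp <- tiny_sp()
  cs <- generate_case("chronic", sp, seed = 5)
  expect_s3_class(cs, "oct_case")
  expect_length(cs$slices, 25)
  expect_identical(vapply(cs$slices, `[[`, integer(1), "slice_index"),
                   0:24)
  expect_gte(sum(vapply(cs$slices, `[[`, logical(1), "is_lesion_cut")), 1)
  no <- generate_case("normal", sp, seed = 5)
  expect_identical(sum(vapply(no$slices, `[[`, logical(1),
                              "is_lesion_cut")), 0L)
  expect_identical(generate_case("acute", sp, seed = 3),
                   generate_case("acute", sp, seed = 3))
})

test_that("datasets conserve counts, ids and determinism", {
  sp <- tiny_sp()
  ds <- generate_dataset(2, 3, 1, sp, seed = 77)
  expect_length(ds, 6)
  expect_identical(anyDuplicated(vapply(ds, `[[`, character(1), "case_id")),
                   0L)
  expect_identical(sum(vapply(ds, function(cs) length(cs$slices),
                              integer(1))), 6L * 25L)
  counts <- table(factor(vapply(ds, `[[`, character(1), "label"),
                         levels = c("normal", "acute", "chronic")))
  expect_equal(as.integer(counts), c(2L, 3L, 1L))
  expect_identical(generate_dataset(2, 3, 1, sp, seed = 77), ds)
  expect_length(generate_dataset(0, 0, 0, sp, seed = 1), 0)
  expect_error(generate_dataset(-1, 0, 0, sp), "non-negative")
})
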