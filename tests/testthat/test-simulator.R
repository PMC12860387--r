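test_that("the single-cell generator plants marker structure deterministically", {
  r1 <- generate_synthetic_scrna(200, 30, 1, marker_fold = 5, seed = 2)
  expect_true(all(r1$cell_types == 1))

  r2 <- generate_synthetic_scrna(300, 40, 3, marker_fold = 5, seed = 9)
  r3 <- generate_synthetic_scrna(300, 40, 3, marker_fold = 5, seed = 9)
  expect_identical(r2$counts, r3$counts)
  expect_true(all(r2$counts >= 0) && all(r2$counts == floor(r2$counts)))
  expect_error(generate_synthetic_scrna(100, 5, 10), "n_types")
  expect_error(generate_synthetic_scrna(100, 20, 2, marker_fold = 1), "marker_fold")
})

test_that("marker genes are enriched close to the requested fold", {
  ref <- generate_synthetic_scrna(2000, 100, 4, marker_fold = 10,
                                  base_rate = 1, seed = 7)
  for (t in 1:4) {
    g <- ref$marker_map[[t]][1]
    m_in <- mean(ref$counts[ref$cell_types == t, g])
    m_out <- mean(ref$counts[ref$cell_types != t, g])
    expect_gt(m_in / m_out, 7)
    expect_lt(m_in / m_out, 13)
  }
})

test_that("pseudo-spot proportions are exact sampled-cell ratios on the simplex", {
  ref <- tiny_ref(3)
  ps <- simulate_pseudospots(ref, pseudospot_config(40, seed = 21,
                                                    downsample_fraction = 1))
  prop <- unclass(ps$proportions)
  expect_true(all(abs(rowSums(prop) - 1) < 1e-9))
  # rows are ratios of integers k / N_c
  counts <- prop * ps$n_cells
  expect_true(all(abs(counts - round(counts)) < 1e-9))
})

test_that("replaying the recorded cell indices reproduces spot expression exactly", {
  ref <- tiny_ref(8)
  ps <- simulate_pseudospots(ref, pseudospot_config(25, seed = 4))
  replay <- t(vapply(ps$sampled_cells, function(idx)
    colSums(ref$counts[idx, , drop = FALSE]), numeric(ncol(ref$counts))))
  expect_identical(unname(as.matrix(ps$pre_downsample$values)), unname(replay))
  # conservation of totals before downsampling
  expect_equal(unname(rowSums(as.matrix(ps$pre_downsample$values))),
               vapply(ps$sampled_cells, function(idx)
                 sum(ref$counts[idx, ]), numeric(1)))
})

test_that("pseudo-spot draws respect the truncation bounds", {
  ref <- tiny_ref(2, n_types = 2)
  ps <- simulate_pseudospots(ref, pseudospot_config(200, mu_types = 3,
                                                    sigma_types = 2, seed = 6))
  expect_true(all(ps$n_types_drawn %in% c(1, 2)))
  expect_true(all(ps$n_cells >= 1))

  one <- generate_synthetic_scrna(50, 20, 1, marker_fold = 4, seed = 1)
  ps1 <- simulate_pseudospots(one, pseudospot_config(10, seed = 2))
  expect_true(all(unclass(ps1$proportions) == 1))
})

test_that("binomial thinning is exact at the boundaries and unbiased", {
  m <- spot_matrix(matrix(c(100, 3, 0, 7), 2, 2), c("s1", "s2"), c("a", "b"))
  expect_identical(downsample_counts(m, 1)$values, m$values)
  tiny <- downsample_counts(m, 1e-12, seed = 1)
  expect_true(all(as.matrix(tiny$values) == 0))
  expect_error(downsample_counts(m, 0), "fraction")
  expect_error(downsample_counts(m, 1.2), "fraction")

  # mean over replicates of a single entry of 100 at fraction 0.5
  draws <- vapply(1:10000, function(i)
    as.matrix(downsample_counts(m, 0.5, seed = i)$values)[1, 1], numeric(1))
  expect_gt(mean(draws), 48)
  expect_lt(mean(draws), 52)
  # thinned counts never exceed the originals
  one <- downsample_counts(m, 0.3, seed = 5)
  expect_true(all(as.matrix(one$values) <= as.matrix(m$values)))
  expect_identical(downsample_counts(m, 0.3, seed = 5)$values, one$values)
})

test_that("synthetic slides have consistent geometry, labels and imagery", {
  sl <- generate_synthetic_slide(5, 6, spacing_px = 30, n_regions = 3,
                                 image_margin_px = 40, seed = 13)
  expect_equal(nrow(sl$coords), 30)
  expect_equal(sort(unique(sl$region_ids)), 1:3)
  # every spot centre inside the image
  expect_true(all(sl$coords$x >= 1 & sl$coords$x <= dim(sl$image)[2]))
  expect_true(all(sl$coords$y >= 1 & sl$coords$y <= dim(sl$image)[1]))

  # geometric oracle: re-derive labels by point-in-rectangle-union
  derived <- vapply(seq_len(nrow(sl$coords)), function(i) {
    x <- sl$coords$x[i]; y <- sl$coords$y[i]
    hits <- which(vapply(sl$region_geometry, function(rects)
      any(x >= rects$xmin & x <= rects$xmax &
          y >= rects$ymin & y <= rects$ymax), logical(1)))
    as.integer(names(sl$region_geometry))[hits[1]]
  }, integer(1))
  expect_identical(derived, sl$region_ids)

  single <- generate_synthetic_slide(3, 3, 30, n_regions = 1, seed = 2)
  expect_true(all(single$region_ids == 1))
  expect_error(generate_synthetic_slide(3, 3, 30, n_regions = 10), "regions")
})

test_that("patches at scale 50 stay inside the image when the margin allows", {
  sl <- generate_synthetic_slide(4, 4, spacing_px = 30, n_regions = 2,
                                 image_margin_px = 25, seed = 3)
  pats <- extract_patches(sl$image, sl$coords, scales = 50, out_size = 32)
  expect_true(all(pats$provenance$padded_fraction == 0))
})

test_that("slide spots carry planted region-dominant compositions", {
  ref <- tiny_ref(4, n_types = 3)
  sl <- generate_synthetic_slide(4, 4, 30, n_regions = 3, seed = 5)
  ds <- simulate_slide_spots(ref, sl, dominant_weight = 0.8, seed = 6)
  expect_s3_class(ds, "st_dataset")
  truth <- unclass(ds$proportions)
  dom <- ((sl$region_ids - 1) %% 3) + 1
  # with 0.8 extra mass the planted type should dominate almost everywhere
  expect_gt(mean(max.col(truth) == dom), 0.8)
  # determinism
  ds2 <- simulate_slide_spots(ref, sl, dominant_weight = 0.8, seed = 6)
  expect_identical(ds$expression$values, ds2$expression$values)
})

test_that("artifact perturbations are deterministic, bounded and size-preserving", {
  sl <- generate_synthetic_slide(4, 4, 30, n_regions = 2,
                                 image_margin_px = 40, seed = 8)
  img <- sl$image
  for (kind in c("crack", "fold", "stain", "crack_fold_stain")) {
    out <- apply_artifact(img, kind, severity = 0.3, seed = 4)
    expect_identical(dim(out), dim(img))
    expect_identical(apply_artifact(img, kind, severity = 0.3, seed = 4), out)
    expect_false(identical(out, img))
  }
  expect_error(apply_artifact(img, "smudge"), "kind")
  expect_error(apply_artifact(img, "crack", severity = 0), "severity")
})

test_that("a crack at severity 0.2 modifies a small fraction of pixels", {
  sl <- generate_synthetic_slide(6, 6, 40, n_regions = 2,
                                 image_margin_px = 60, seed = 17)
  out <- apply_artifact(sl$image, "crack", severity = 0.2, seed = 3)
  frac <- mean(apply(abs(out - sl$image), c(1, 2), max) > 1e-9)
  expect_gt(frac, 0.001)
  expect_lt(frac, 0.05)
})
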