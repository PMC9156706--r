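test_that("frames have the task geometry and 8-bit integer intensities", {
  withr::with_seed(1, {
    fc <- simulate_frame("fat")
    fr <- simulate_frame("spinal_cord", geometry = "regress")
    expect_equal(dim(fc$pixels), c(241L, 181L))  # depth x width
    expect_equal(dim(fr$pixels), c(681L, 241L))
    for (f in list(fc, fr)) {
      expect_true(is.integer(f$pixels))
      expect_gte(min(f$pixels), 0)
      expect_lte(max(f$pixels), 255)
    }
  })
})

test_that("the epidural dark gap starts at round(distance / pixel size)", {
  withr::with_seed(2, {
    fr <- simulate_frame("epidural_space", distance_um = 625)
    r <- rowMeans(fr$pixels)
    # 625 / 6.25 = 100 background rows; tissue surface at row 101
    expect_true(all(r[1:99] < 40))
    expect_gt(r[101], 80)
    expect_equal(detect_surface_distance(fr), 625)

    f0 <- simulate_frame("epidural_space", distance_um = 0)
    expect_equal(detect_surface_distance(f0), 0)
    expect_gt(rowMeans(f0$pixels)[1], 100)  # tissue from the first row
  })
})

test_that("distance labels are validated against label and frame depth", {
  expect_error(simulate_frame("fat", distance_um = 500), "only.*epidural")
  expect_error(simulate_frame("epidural_space", distance_um = 2000),
               "outside the frame depth")
  expect_error(simulate_frame("epidural_space"), "require")
  expect_error(simulate_subject(1, 2, distance_range_um = c(200, 5000)),
               "within the frame depth")
})

test_that("generation is bit-identical under a fixed seed", {
  d1 <- simulate_subject(1, frames_per_layer = 3, seed = 99)
  d2 <- simulate_subject(1, frames_per_layer = 3, seed = 99)
  expect_identical(d1$frame, d2$frame)
  s1 <- simulate_insertion_sequence(c(2, 2, 2, 2, 2), seed = 99)
  s2 <- simulate_insertion_sequence(c(2, 2, 2, 2, 2), seed = 99)
  expect_identical(s1$frame, s2$frame)
})

test_that("subject datasets have balanced layers and in-range distances", {
  d <- simulate_subject(4, frames_per_layer = 10, seed = 5)
  expect_equal(nrow(d), 50)
  expect_true(all(table(d$label) == 10))
  expect_true(all(d$subject_id == 4))
  epi <- d$distance_um[d$label == "epidural_space"]
  expect_true(all(epi >= 200 & epi <= 1400))
  expect_true(all(is.na(d$distance_um[d$label != "epidural_space"])))

  dr <- simulate_subject(1, frames_per_layer = 25, task = "regress",
                         distance_range_um = c(200, 2500),
                         layers = "epidural_space", seed = 6)
  expect_equal(nrow(dr), 25)
  expect_true(all(dr$distance_um >= 200 & dr$distance_um <= 2500))
})

test_that("interspinous ligament decays slower than ligamentum flavum", {
  # per-frame log-linear decay fit; ligament has the longest attenuation
  withr::with_seed(8, {
    app <- default_appearances()
    lig <- replicate(30, frame_features(
      simulate_frame("interspinous_ligament", app))["attenuation"])
    fla <- replicate(30, frame_features(
      simulate_frame("ligamentum_flavum", app))["attenuation"])
    expect_gt(mean(lig), mean(fla))
  })
})

test_that("insertion sequences follow the puncture order and segment lengths", {
  seqd <- fixture("default_sequence", function() {
    simulate_insertion_sequence(seed = 301)
  })
  expect_equal(nrow(seqd), 1150)
  expect_equal(as.character(seqd$label[800]), "interspinous_ligament")
  expect_equal(as.character(seqd$label[801]), "ligamentum_flavum")
  expect_equal(as.vector(table(seqd$label)), c(100, 700, 100, 100, 150))
  epi <- seqd$distance_um[seqd$label == "epidural_space"]
  expect_true(all(diff(epi) < 0))  # the needle advances toward the dura

  deg <- simulate_insertion_sequence(c(0, 0, 0, 0, 5), seed = 1)
  expect_equal(nrow(deg), 5)
  expect_true(all(deg$label == "spinal_cord"))
})

test_that("adjacent tissue classes separate by > 2 pooled SD on some feature", {
  d <- fixture("signature_study", function() {
    simulate_study(n_subjects = 4, frames_per_layer = 15, seed = 77)
  })
  feats <- t(vapply(d$frame, frame_features, numeric(4)))
  lab <- as.character(d$label)
  lv <- tissue_labels()
  for (k in 1:4) {
    a <- feats[lab == lv[k], , drop = FALSE]
    b <- feats[lab == lv[k + 1], , drop = FALSE]
    sep <- vapply(seq_len(ncol(feats)), function(j) {
      sp <- sqrt((var(a[, j]) + var(b[, j])) / 2)
      abs(mean(a[, j]) - mean(b[, j])) / sp
    }, numeric(1))
    expect_gt(max(sep), 2)
  }
})

test_that("the confusable configuration makes fat and cord indistinguishable", {
  app <- default_appearances(confusable = TRUE)
  fat <- app[app$label == "fat", -1]
  cord <- app[app$label == "spinal_cord", -1]
  expect_equal(unname(as.numeric(fat)), unname(as.numeric(cord)))
  # adjacent-stage contrasts stay intact
  expect_gt(app$attenuation_length_px[app$label == "interspinous_ligament"],
            app$attenuation_length_px[app$label == "fat"])
})
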