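test_that("splitting reproduces the published partition sizes", {
  sp <- split_dataset(seq_len(1954), seed = 3)
  expect_equal(lengths(sp), c(train = 1367, val = 391, test = 196))
  sp10 <- split_dataset(seq_len(10), seed = 1)
  expect_equal(lengths(sp10), c(train = 7, val = 2, test = 1))
  expect_error(split_dataset(list()), "empty")
  expect_error(split_dataset(1:5, ratios = c(0.5, 0.3, 0.1)), "sum to 1")
})

test_that("splits partition the input deterministically for every n", {
  for (n in c(1:20, sample(21:500, 25))) {
    sp <- split_dataset(seq_len(n), seed = n)
    all_items <- c(sp$train, sp$val, sp$test)
    expect_equal(sort(all_items), seq_len(n))       # disjoint and exhaustive
    sp2 <- split_dataset(seq_len(n), seed = n)
    expect_identical(sp, sp2)                       # deterministic
  }
})

test_that("offline augmentation expands by the exact factor", {
  set.seed(1)
  p <- scene_params(size = 48L, lambda = 4, radius_range = c(4, 8))
  items <- generate_dataset(3, p, seed = 5)
  expect_length(augment_offline(items, factor = 4, seed = 1), 12)
  expect_identical(augment_offline(items, factor = 1, seed = 1), items)
  expect_error(augment_offline(items, factor = 0), "factor")
})

test_that("box geometry transforms consistently with the pixels", {
  it <- annotated_image("a", boxes = rbind(c(0, 0.2, 0.5, 0.1, 0.1)))
  fl <- berrydetr:::flip_h(it)
  expect_equal(unname(fl$boxes[1, ]), c(0, 0.8, 0.5, 0.1, 0.1))
  fv <- berrydetr:::flip_v(it)
  expect_equal(unname(fv$boxes[1, ]), c(0, 0.2, 0.5, 0.1, 0.1))
  # augmented boxes always keep centres inside the frame
  set.seed(2)
  p <- scene_params(size = 48L, lambda = 6, radius_range = c(4, 8))
  items <- generate_dataset(4, p, seed = 11)
  aug <- augment_offline(items, factor = 6, seed = 3)
  for (a in aug)
    if (nrow(a$boxes))
      expect_true(all(a$boxes[, 2:3] >= 0 & a$boxes[, 2:3] <= 1))
})

test_that("YOLO and COCO round trips are lossless at format precision", {
  set.seed(3)
  boxes <- cbind(sample(0:2, 100, TRUE), matrix(runif(400, 0.2, 0.7), 100))
  boxes[, 4:5] <- pmin(boxes[, 4:5], 0.25)
  it <- annotated_image("img1", boxes = boxes)
  # YOLO text round trip
  tf <- tempfile(fileext = ".txt")
  write_yolo(it, tf)
  rt <- read_yolo(tf)
  expect_lt(max(abs(rt$boxes - it$boxes)), 1e-6)
  # YOLO -> COCO -> YOLO round trip at 640 x 640
  tj <- tempfile(fileext = ".json")
  write_coco(list(it), tj, sizes = c(640, 640))
  cc <- read_coco(tj)
  expect_lt(max(abs(cc[[1]]$boxes - it$boxes)), 1e-6)
  # the arithmetic of the conversion itself
  one <- annotated_image("x", boxes = rbind(c(0, 0.5, 0.5, 0.1, 0.2)))
  tj2 <- tempfile(fileext = ".json")
  write_coco(list(one), tj2, sizes = c(640, 640))
  j <- jsonlite::read_json(tj2)
  expect_equal(unlist(j$annotations[[1]]$bbox), c(288, 256, 64, 128))
  # empty label file -> zero boxes; malformed line names the file
  empty <- tempfile(fileext = ".txt"); file.create(empty)
  expect_equal(nrow(read_yolo(empty)$boxes), 0)
  bad <- tempfile(fileext = ".txt"); writeLines("0 0.5 x 0.1 0.1", bad)
  expect_error(read_yolo(bad), "malformed")
  badj <- tempfile(fileext = ".json"); writeLines("{", badj)
  expect_error(read_coco(badj), "malformed")
})

test_that("the scene generator is deterministic and label-faithful", {
  p <- scene_params(size = 96L, lambda = 8, radius_range = c(4, 7),
                    occlusion_fraction = 0)
  a <- generate_scene(p, seed = 42)
  b <- generate_scene(p, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a$img, generate_scene(p, seed = 43)$img))
  # occlusion 0: box count equals berry count (no berry fully lost)
  set.seed(1)
  for (sd in 1:5) {
    sc <- generate_scene(p, seed = sd)
    expect_gt(nrow(sc$boxes), 0)
  }
})

test_that("box sizes track the configured radius range", {
  p <- scene_params(size = 640L, lambda = 30, radius_range = c(3, 6),
                    occlusion_fraction = 0)
  sc <- generate_scene(p, seed = 9)
  wh <- sc$boxes[, 4:5] * 640
  # diameter 6..12 px plus the anti-aliased rim
  expect_true(all(wh >= 6 - 1e-9 & wh <= 14))
  expect_error(scene_params(radius_range = c(1, 4)), "radius")
  expect_error(scene_params(occlusion_fraction = 1), "occlusion")
})

test_that("rendered berry centroids match their labels to sub-pixel accuracy", {
  p <- scene_params(size = 96L, lambda = 1e-9, radius_range = c(8, 10),
                    occlusion_fraction = 0, clutter = 0, red_fraction = 1,
                    illumination_range = c(1, 1))
  for (sd in 1:5) {
    sc <- generate_scene(p, seed = sd)
    expect_equal(nrow(sc$boxes), 1)
    # locate the red blob: red channel dominates green strongly on berries
    mask <- sc$img[, , 1] - sc$img[, , 2] > 0.2
    ys <- row(mask)[mask] - 1; xs <- col(mask)[mask] - 1
    cx <- mean(xs) + 0.5; cy <- mean(ys) + 0.5
    expect_lt(abs(cx - sc$boxes[1, "cx"] * 96), 1)
    expect_lt(abs(cy - sc$boxes[1, "cy"] * 96), 1)
  }
})
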