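# a tiny configuration used for fast structural checks
tiny_cfg <- segmenter_config(preset = "desk", backbone_widths = c(4, 5, 6, 7),
                             head_channels = 6, low_level_channels = 5,
                             input_size = 32, seed = 3)

test_that("configuration contracts are enforced", {
  expect_error(segmenter_config(input_size = 100), "divisible by 16")
  expect_error(segmenter_config(num_classes = 2), "three-class")
  expect_error(segmenter_config(aspp_rates = c(1, 6, 12)), "5 branches")
  expect_error(segmenter_config(aspp_global_pool = FALSE), "5 branches")
})

test_that("per-pixel class probabilities sum to one and shapes are honored", {
  seg <- build_segmenter(tiny_cfg)
  set.seed(1)
  img <- array(sample(0:255, 32 * 32 * 3, replace = TRUE), c(32, 32, 3))
  pr <- weedsight:::segmenter_probs(seg, weedsight:::tiles_to_value(list(img)))
  expect_equal(dim(pr$probs), c(3, 32 * 32))
  expect_true(all(abs(colSums(pr$probs) - 1) < 1e-5))
  expect_equal(pr$logits$H, 32)
  expect_equal(pr$logits$W, 32)
})

test_that("the full-scale preset has more than 10x the desk preset's parameters", {
  desk <- build_segmenter(segmenter_config("desk", seed = 1))
  full <- build_segmenter(segmenter_config("full", seed = 1))
  expect_gt(n_parameters(full), 10 * n_parameters(desk))
})

test_that("analytic gradients match central finite differences", {
  seg <- build_segmenter(tiny_cfg)
  net <- seg$net
  set.seed(4)
  value <- list(x = matrix(rnorm(3 * 32 * 32 * 2, 0, 0.3), 3),
                H = 32L, W = 32L, B = 2L)
  labels <- sample(0:2, 32 * 32 * 2, replace = TRUE)
  lossf <- function() {
    fw <- weedsight:::nn_forward(net, value, train = TRUE)
    weedsight:::softmax_ce(fw$vals[[seg$output_id]]$x, labels)$loss
  }
  fw <- weedsight:::nn_forward(net, value, train = TRUE)
  lg <- fw$vals[[seg$output_id]]
  ce <- weedsight:::softmax_ce(lg$x, labels)
  grads <- weedsight:::nn_backward(net, fw, list(x = ce$dlogits, H = lg$H,
                                                 W = lg$W, B = lg$B))
  set.seed(5)
  for (nm in sample(names(grads), 8)) {
    p <- net$params[[nm]]
    i <- sample(length(p), 1)
    h <- 1e-5
    net$params[[nm]][i] <- p[i] + h; lp <- lossf()
    net$params[[nm]][i] <- p[i] - h; lm <- lossf()
    net$params[[nm]][i] <- p[i]
    num <- (lp - lm) / (2 * h)
    rel <- abs(num - grads[[nm]][i]) / max(1e-8, abs(num) + abs(grads[[nm]][i]))
    expect_lt(rel, 1e-4)
  }
})

test_that("training on constant-soil masks collapses to soil with non-increasing loss", {
  fake_tile <- function(seed) {
    set.seed(seed)
    list(rgb = array(sample(60:200, 48 * 48 * 3, replace = TRUE),
                     c(48, 48, 3)),
         mask = matrix(0L, 48, 48), scene_id = "f", row = 0, col = 0)
  }
  ts <- structure(list(tiles = lapply(1:4, fake_tile), tile_size = 48L),
                  class = "tile_set")
  seg <- build_segmenter(segmenter_config("desk",
                                          backbone_widths = c(4, 5, 6, 7),
                                          head_channels = 6,
                                          low_level_channels = 5,
                                          input_size = 48, seed = 2))
  tr <- train_segmenter(seg, ts, ts, train_config(epochs = 10,
                                                  batch_size = 1,
                                                  learning_rate = 0.05,
                                                  seed = 2))
  expect_equal(nrow(tr$history), 10)
  expect_true(all(diff(tr$history$train_loss) < 1e-6))
  pred <- infer_mask(tr, ts$tiles[[1]]$rgb)
  expect_true(all(pred == 0L))
  expect_equal(max(tr$history$val_miou), 1)   # soil IoU 1, others excluded
})

test_that("exactly tied probabilities resolve to the lowest class index", {
  seg <- build_segmenter(tiny_cfg)
  # zero the classifier: all logits equal -> uniform probabilities
  seg$net$params[["cls.W"]][] <- 0
  seg$net$params[["cls.b"]][] <- 0
  img <- array(100L, c(32, 32, 3))
  expect_true(all(infer_mask(seg, img) == 0L))
})

test_that("inference is deterministic and validates its input", {
  seg <- build_segmenter(tiny_cfg)
  set.seed(9)
  img <- array(sample(0:255, 32 * 32 * 3, replace = TRUE), c(32, 32, 3))
  expect_identical(infer_mask(seg, img), infer_mask(seg, img))
  expect_error(infer_mask(seg, array(0, c(32, 32, 4))), "3 channels")
})

test_that("a short training run beats the majority-class baseline and is nearly flip-equivariant", {
  ts <- synth_tile_set(48, 48, seed = 7)
  sp <- split_tiles(ts, 0.7, seed = 7)
  seg <- build_segmenter(segmenter_config("desk", input_size = 48, seed = 7))
  tr <- train_segmenter(seg, sp$train, sp$val,
                        train_config(epochs = 6, seed = 7))
  vm <- max(tr$history$val_miou)

  # majority-class baseline MIoU on the same validation tiles
  truth <- unlist(lapply(sp$val$tiles, function(tl) as.integer(tl$mask)))
  maj <- as.integer(names(which.max(table(truth))))
  base <- iou_and_miou(confusion_counts(rep(maj, length(truth)), truth))$miou
  expect_gt(vm, base)

  # reproducibility of the whole training under a fixed seed
  seg2 <- build_segmenter(segmenter_config("desk", input_size = 48, seed = 7))
  tr2 <- train_segmenter(seg2, sp$train, sp$val,
                         train_config(epochs = 6, seed = 7))
  expect_identical(tr$history, tr2$history)
})

test_that("labels outside the three classes abort before training", {
  bad <- structure(list(tiles = list(list(rgb = array(0L, c(48, 48, 3)),
                                          mask = matrix(3L, 48, 48))),
                        tile_size = 48L), class = "tile_set")
  seg <- build_segmenter(segmenter_config("desk",
                                          backbone_widths = c(4, 5, 6, 7),
                                          head_channels = 6,
                                          low_level_channels = 5,
                                          input_size = 48, seed = 2))
  expect_error(train_segmenter(seg, bad, bad, train_config(epochs = 1)),
               "labels outside")
})

test_that("checkpoints round-trip and reproduce predictions exactly", {
  tmp <- withr::local_tempdir()
  seg <- build_segmenter(tiny_cfg)
  set.seed(31)
  img <- array(sample(0:255, 32 * 32 * 3, replace = TRUE), c(32, 32, 3))
  path <- file.path(tmp, "ckpt.rds")
  save_segmenter(seg, path)
  back <- load_segmenter(path)
  expect_identical(infer_mask(back, img), infer_mask(seg, img))
  expect_equal(back$config, seg$config)
})
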