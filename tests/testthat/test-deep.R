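test_that("GapNet architecture audit: 8 conv, 5 pool, 3 fc, SELU, no BN", {
  g <- build_gapnet(3, seed = 1)
  tab <- table(g$layers$type)
  expect_equal(unname(tab["conv"]), 8L)
  expect_equal(unname(tab["pool"]), 5L)
  expect_equal(unname(tab["fc"]), 3L)
  expect_equal(g$activation, "selu")
  expect_false(any(grepl("batch|relu", g$layers$name, ignore.case = TRUE)))
  expect_equal(ncol(g$fc[[1]]$W), 256L)   # penultimate width
})

test_that("penultimate feature lengths are fixed and size-robust", {
  g <- build_gapnet(3, seed = 1)
  for (side in c(32, 64, 96)) {
    x <- array(runif(side * side * 3), c(side, side, 3))
    expect_length(ihcloc:::gapnet_forward(g, x)$penultimate, 256)
  }
  for (nm in c("googlenet", "resnet50", "densenet201")) {
    e <- ihcloc:::build_encoder(nm, seed = 1)
    x <- array(runif(48 * 48 * 3), c(48, 48, 3))
    expect_length(ihcloc:::encoder_forward(e, x)$penultimate, 1000)
  }
  expect_equal(backbone_spec("gapnet_pl")$feature_dim, 256L)
  expect_equal(backbone_spec("resnet18")$feature_dim, 1000L)
})

test_that("extraction is deterministic and averages over patches", {
  ch <- make_channels("ii", size = 80, seed = 3)
  ps <- select_patches(ch, n = 3, size = 24, image_ref = "img")
  spec <- backbone_spec("gapnet_pl", weights = "random", seed = 5)
  d1 <- extract_deep(ps, spec)
  d2 <- extract_deep(ps, spec)
  expect_identical(d1$features, d2$features)
  expect_equal(d1$image_vector, colMeans(d1$features), tolerance = 1e-12)
  expect_equal(dim(d1$features), c(3L, 256L))
  ps1 <- select_patches(ch, n = 1, size = 24)
  d3 <- extract_deep(ps1, spec)
  expect_equal(d3$image_vector, d3$features[1, ], tolerance = 1e-12)
})

test_that("pretrained weights without a file are refused with guidance", {
  expect_error(build_backbone(backbone_spec("resnet50", weights = "pretrained")),
               "weights = 'file'")
  expect_error(build_backbone(backbone_spec("resnet50", weights = "file",
                                            weights_file = "/nope.rds")),
               "not found")
})

test_that("backbone weights round-trip through a file", {
  g <- build_gapnet(3, seed = 42)
  f <- withr::local_tempfile(fileext = ".rds")
  save_backbone(g, f)
  g2 <- build_backbone(backbone_spec("gapnet_pl", weights = "file",
                                     weights_file = f, seed = 1))
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_equal(ihcloc:::gapnet_forward(g2, x)$penultimate,
               ihcloc:::gapnet_forward(g, x)$penultimate, tolerance = 1e-12)
})

test_that("fine-tuning reduces loss and fits separable patches", {
  mk <- function(cl, k, base) lapply(seq_len(k), function(i) {
    sp <- synth_spec(image_size = 48, n_nuclei = 3, nucleus_axes = c(5, 8),
                     ring_width = 4, class_pattern = cl, seed = base + i,
                     noise_sd = 0.02)
    unmix_linear(synth_image(sp)$image)$protein[1:32, 1:32]
  })
  patches <- c(mk("i", 16, 100), mk("ii", 16, 200))
  labels <- rep(c("i", "ii"), each = 16)
  g <- build_gapnet(3, seed = 1)
  ft <- fine_tune(g, patches, labels, epochs = 20, seed = 1, lr = 5e-3)
  expect_lt(ft$loss_trace[2], ft$loss_trace[1])       # 1 epoch already descends
  expect_gte(ft$train_accuracy, 0.8)                  # separable in <= 20 epochs
  expect_equal(ncol(ft$model$fc[[3]]$W), 2L)          # replaced output head
  e <- ihcloc:::build_encoder("googlenet", seed = 1)
  fte <- fine_tune(e, patches[c(1:4, 17:20)], labels[c(1:4, 17:20)],
                   epochs = 2, seed = 1)
  expect_equal(ncol(fte$model$fc_out$W), 2L)
  expect_error(fine_tune(g, patches[1:4], rep("i", 4)), "2 classes")
})

test_that("combined vector is 7104 with the declared block offsets", {
  eng <- setNames(runif(848), paste0("eng", 1:848))
  dims <- c(googlenet = 1000, resnet18 = 1000, resnet50 = 1000,
            resnet101 = 1000, inception_v3 = 1000, densenet201 = 1000,
            gapnet_pl = 256)
  deep <- lapply(dims, function(d) runif(d))
  v <- combine_features(eng, deep)
  expect_length(v, 7104)
  expect_equal(unname(v[1:848]), unname(eng))
  expect_true(all(startsWith(names(v)[6849:7104], "deep.gapnet_pl")))
  expect_error(combine_features(eng, deep[-3]), "resnet50")
  deep_bad <- deep; deep_bad$gapnet_pl <- runif(10)
  expect_error(combine_features(eng, deep_bad), "gapnet_pl")
  expect_error(combine_features(runif(10), deep), "engineered")
})
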