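# Shared fixtures, generated once per test session.

# Continuous (unquantized) OD mixture plus its generating truth.
make_od_mixture <- function(class_pattern = "ii", size = 96, seed = 3,
                            noise_sd = 0) {
  sp <- synth_spec(image_size = size, n_nuclei = 6, nucleus_axes = c(6, 10),
                   ring_width = 5, class_pattern = class_pattern,
                   noise_sd = noise_sd, seed = seed)
  out <- synth_image(sp)
  od <- array(0, c(size, size, 3))
  od[] <- cbind(as.vector(out$truth$od_dna), as.vector(out$truth$od_protein)) %*%
    unclass(out$truth$basis)
  list(od = od, truth = out$truth, image = out$image)
}

# Unmixed channels of one synthetic image (used by patch/feature tests).
make_channels <- function(class_pattern = "iii", size = 96, seed = 5,
                          noise_sd = 0.02) {
  sp <- synth_spec(image_size = size, n_nuclei = 6, nucleus_axes = c(6, 10),
                   ring_width = 5, class_pattern = class_pattern,
                   noise_sd = noise_sd, seed = seed)
  unmix_linear(synth_image(sp)$image)
}

# A small synthetic dataset on disk, created once and shared.
shared_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "ihcloc_shared_ds")
      cache <<- synth_dataset(dir, n_proteins = 6, images_per_state = c(2, 3),
                              biomarker_fraction = 0.5,
                              spec = synth_spec(image_size = 80, n_nuclei = 5,
                                                nucleus_axes = c(5, 9),
                                                ring_width = 4),
                              seed = 20L)
    }
    cache
  }
})

# Seven quickly trained single classifiers over named toy feature blocks,
# plus a generator of full feature vectors (used by biomarker tests).
toy_seven_models <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(99)
      backbones <- c("googlenet", "resnet18", "resnet50", "resnet101",
                     "inception_v3", "densenet201", "gapnet_pl")
      centers <- list(i = c(0, 0), ii = c(3, 0), iii = c(0, 3))
      y <- rep(c("i", "ii", "iii"), each = 12)
      models <- list()
      for (nm in backbones) {
        X <- t(vapply(y, function(cl) centers[[cl]] + rnorm(2, 0, 0.4),
                      numeric(2)))
        colnames(X) <- paste0("deep.", nm, ".f", 1:2)
        models[[nm]] <- train_svm(X, y, grid = list(c = 10, g = 0.5), seed = 1)
      }
      feature_for <- function(cl, noise = 0.4) {
        v <- unlist(lapply(backbones, function(nm)
          setNames(centers[[cl]] + rnorm(2, 0, noise),
                   paste0("deep.", nm, ".f", 1:2))))
        v
      }
      cache <<- list(models = models, feature_for = feature_for)
    }
    cache
  }
})
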