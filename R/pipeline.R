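# Pipeline orchestration: one configuration drives
# unmix -> patchify -> featurize -> deep-extract -> select -> train ->
# detect, with CSV artifacts per stage and a JSON summary.

#' Default pipeline configuration
#'
#' All tunable parameters of every stage, overridable via
#' [run_pipeline()]'s `config` (a list or a YAML file with the same
#' structure). Unknown keys are rejected.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    manifest = NULL, workdir = NULL, biomarker_manifest = NULL,
    seed = 1L,
    unmix = list(method = "lin"),
    patch = list(n = 205L, size = 75L, max_overlap = 0.25),
    deep_patch = list(n = 35L, size = 224L),
    features = list(wavelet = "db4"),
    selection = list(f_enter = 3.84, f_remove = 2.71, max_k = 97L),
    svm = list(grid = small_svm_grid()),
    eval = list(mode = "per_protein", k = 10L),
    backbones = BACKBONE_ORDER,
    weights = "random",
    biomarker = list(alpha = 0.05, variant = "student")
  )
}

merge_config <- function(user) {
  base <- default_config()
  check <- function(u, b, path = "") {
    bad <- setdiff(names(u), names(b))
    if (length(bad))
      stop("unknown config key(s): ", paste0(path, bad, collapse = ", "))
  }
  check(user, base)
  for (nm in names(user))
    if (is.list(base[[nm]]) && is.list(user[[nm]]) && nm != "svm")
      check(user[[nm]], base[[nm]], paste0(nm, "$"))
  modifyList(base, user)
}

# Minimal flat JSON writer for stage summaries (numbers, strings, vectors).
to_json <- function(x, indent = "") {
  enc <- function(v) {
    if (is.character(v)) paste0('"', gsub('"', '\\\\"', v), '"')
    else if (is.logical(v)) ifelse(v, "true", "false")
    else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }
  if (is.list(x)) {
    inner <- vapply(names(x), function(nm)
      paste0(indent, '  "', nm, '": ', to_json(x[[nm]], paste0(indent, "  "))),
      "")
    paste0("{\n", paste(inner, collapse = ",\n"), "\n", indent, "}")
  } else if (length(x) == 1) enc(x)
  else paste0("[", paste(enc(x), collapse = ", "), "]")
}

#' Deep feature matrix for a whole manifest
#'
#' Unmixes each image, selects the deep-model patch set and extracts the
#' penultimate features of every requested backbone (mean over patches).
#'
#' @param man a `DatasetManifest`.
#' @param backbones character vector of backbone names.
#' @param n_patches,patch_size deep patch defaults (35 patches of
#'   224 px; tests and desk-scale runs use smaller values).
#' @param seed weight seed shared by the backbones.
#' @param weights,weights_files passed to [backbone_spec()].
#' @param unmix `"lin"` or `"nmf"`; `basis` for LIN.
#' @param basis stain basis.
#' @param loader function(path) -> `IHCImage`.
#' @return Matrix images x sum(feature_dim), block-named columns.
#' @export
deep_featurize_manifest <- function(man, backbones = BACKBONE_ORDER,
                                    n_patches = 35L, patch_size = 224L,
                                    seed = 1L, weights = "random",
                                    weights_files = NULL,
                                    unmix = "lin", basis = default_basis(),
                                    loader = read_image) {
  models <- lapply(backbones, function(nm)
    build_backbone(backbone_spec(nm, weights = weights,
                                 weights_file = weights_files[[nm]],
                                 seed = seed)))
  names(models) <- backbones
  rows <- lapply(seq_len(nrow(man$records)), function(i) {
    img <- loader(man$records$image_path[i])
    ch <- if (unmix == "lin") unmix_linear(img, basis) else unmix_nmf(img, seed = i)
    ps <- suppressWarnings(select_patches(ch, n = n_patches, size = patch_size,
                                          image_ref = man$records$image_path[i]))
    unlist(lapply(backbones, function(nm)
      extract_deep(ps, models[[nm]])$image_vector))
  })
  M <- do.call(rbind, rows)
  rownames(M) <- man$records$image_path
  M
}

#' Train the seven single combined-feature classifiers
#'
#' For each backbone, trains one RBF-SVM on the engineered block plus
#' that backbone's deep block (SDA-reduced on the training data), the
#' models whose 3-score outputs make up the 21-dimensional biomarker
#' score vectors.
#'
#' @param combined images x 7104 feature matrix (named columns).
#' @param labels per-image localization labels.
#' @param max_k SDA cap per model.
#' @param grid,seed SVM settings.
#' @return Named list of seven `TrainedModel`s.
#' @export
train_single_models <- function(combined, labels, max_k = 40L,
                                grid = small_svm_grid(), seed = 1L) {
  eng_cols <- grep("^(dna|har|lbp)\\.", colnames(combined), value = TRUE)
  models <- lapply(BACKBONE_ORDER, function(nm) {
    cols <- c(eng_cols, grep(paste0("^deep\\.", nm, "\\."),
                             colnames(combined), value = TRUE))
    X <- combined[, cols, drop = FALSE]
    sel <- suppressWarnings(sda_select(X, labels, max_k = max_k))
    if (length(sel$selected)) X <- X[, sel$selected, drop = FALSE]
    train_svm(X, labels, grid = grid, seed = seed)
  })
  names(models) <- BACKBONE_ORDER
  models
}

#' Run the full pipeline
#'
#' Executes featurization (engineered + deep), feature selection,
#' cross-validated training of the final combined classifier, training
#' of the seven single classifiers, and biomarker detection, writing a
#' CSV artifact per stage and a `summary.json` into the work directory.
#' Existing feature artifacts are reused on re-runs (logged as
#' "cached").
#'
#' @param config list or YAML path; see [default_config()] for the
#'   schema. `manifest` and `workdir` are required; `biomarker_manifest`
#'   defaults to `manifest`.
#' @param loader function(path) -> `IHCImage`.
#' @return list: `config`, `cv_report` (`EvalReport`), `models`,
#'   `final_model`, `report` (`TranslocationReport`), `paths`.
#' @export
run_pipeline <- function(config, loader = read_image) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config)
  if (is.null(cfg$manifest) || is.null(cfg$workdir))
    stop("config must set 'manifest' and 'workdir'")
  dir.create(cfg$workdir, showWarnings = FALSE, recursive = TRUE)
  logf <- function(...) message("[ihcloc] ", sprintf(...))

  man <- if (inherits(cfg$manifest, "DatasetManifest")) cfg$manifest
         else load_manifest(cfg$manifest)
  bman <- if (is.null(cfg$biomarker_manifest)) man
          else if (inherits(cfg$biomarker_manifest, "DatasetManifest")) cfg$biomarker_manifest
          else load_manifest(cfg$biomarker_manifest)
  logf("stage unmix+patchify+featurize: %d modeling images, patches n=%d size=%d",
       nrow(man$records), cfg$patch$n, cfg$patch$size)

  art <- function(f) file.path(cfg$workdir, f)
  load_or <- function(file, fun) {
    if (file.exists(art(file))) {
      logf("stage %s: cached", file)
      as.matrix(read.csv(art(file), row.names = 1, check.names = FALSE))
    } else {
      M <- fun()
      write.csv(M, art(file))
      M
    }
  }
  feats_of <- function(m, tag) {
    eng <- load_or(paste0("features_engineered_", tag, ".csv"), function()
      featurize_manifest(m, n_patches = cfg$patch$n, patch_size = cfg$patch$size,
                         wavelet = cfg$features$wavelet,
                         unmix = cfg$unmix$method, loader = loader))
    deep <- load_or(paste0("features_deep_", tag, ".csv"), function()
      deep_featurize_manifest(m, backbones = cfg$backbones,
                              n_patches = cfg$deep_patch$n,
                              patch_size = cfg$deep_patch$size,
                              seed = cfg$seed, weights = cfg$weights,
                              unmix = cfg$unmix$method, loader = loader))
    cbind(eng, deep)
  }
  combined <- feats_of(man, "modeling")

  labels <- factor(man$records$label, levels = LABEL_LEVELS)
  logf("stage select: SDA cap %d on %d columns", cfg$selection$max_k, ncol(combined))
  sel <- suppressWarnings(sda_select(combined, labels,
                                     f_enter = cfg$selection$f_enter,
                                     f_remove = cfg$selection$f_remove,
                                     max_k = cfg$selection$max_k))
  writeLines(colnames(combined)[sel$selected], art("selected_features.txt"))

  logf("stage train: %s %d-fold cross-validation", cfg$eval$mode, cfg$eval$k)
  cv <- crossval(man, combined[, sel$selected, drop = FALSE],
                 mode = cfg$eval$mode, k = cfg$eval$k, seed = cfg$seed,
                 grid = cfg$svm$grid)
  write.csv(cv$predictions, art("crossval_predictions.csv"), row.names = FALSE)
  final_model <- train_svm(combined[, sel$selected, drop = FALSE], labels,
                           grid = cfg$svm$grid, seed = cfg$seed)
  single <- train_single_models(combined, labels, grid = cfg$svm$grid,
                                seed = cfg$seed)

  logf("stage detect: %d biomarker proteins, alpha=%g",
       length(bman$groups), cfg$biomarker$alpha)
  bio_feats <- if (identical(bman, man)) combined else feats_of(bman, "biomarker")
  report <- detect_biomarkers(single, bio_feats, bman,
                              alpha = cfg$biomarker$alpha,
                              variant = cfg$biomarker$variant,
                              vote_model = final_model)
  write.csv(report, art("biomarker_report.csv"), row.names = FALSE)

  summary <- list(
    n_images = nrow(man$records),
    n_proteins = length(man$groups),
    patch_n = cfg$patch$n, patch_size = cfg$patch$size,
    n_selected_features = length(sel$selected),
    cv_mode = cv$mode, cv_accuracy = cv$accuracy, cv_f1 = cv$f1,
    n_biomarker_proteins = nrow(report),
    n_flagged = sum(report$is_biomarker),
    alpha = cfg$biomarker$alpha, seed = cfg$seed
  )
  writeLines(to_json(summary), art("summary.json"))
  logf("done: cv accuracy %.3f, %d/%d proteins flagged",
       cv$accuracy, sum(report$is_biomarker), nrow(report))
  list(config = cfg, cv_report = cv, models = single,
       final_model = final_model, report = report,
       paths = list(workdir = cfg$workdir, summary = art("summary.json")))
}
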