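# Canonical desk-scale end-to-end biomarker experiment: a 12-protein
# balanced modeling set (3 normal + 3 cancer images each) trains the
# seven single classifiers and the final model; a 20-protein screening
# set (4 normal / 12 cancer images, half the proteins translocating)
# is then screened, and the flags are compared with the generator truth.
run_biomarker_screen <- function(seed) {
  base <- synth_spec(image_size = 80, n_nuclei = 5, nucleus_axes = c(5, 9),
                     ring_width = 4)
  mdir <- file.path(tempdir(), sprintf("ihcloc_e2e_%d", seed))
  mod <- synth_dataset(file.path(mdir, "mod"), n_proteins = 12,
                       images_per_state = c(3, 3), biomarker_fraction = 0,
                       spec = base, seed = seed * 10000 + 1)
  bio <- synth_dataset(file.path(mdir, "bio"), n_proteins = 20,
                       images_per_state = c(4, 12), biomarker_fraction = 0.5,
                       spec = base, seed = seed * 10000 + 2)
  res <- suppressMessages(run_pipeline(list(
    manifest = mod$manifest, biomarker_manifest = bio$manifest,
    workdir = file.path(mdir, "work"),
    patch = list(n = 3L, size = 32L), deep_patch = list(n = 2L, size = 32L),
    selection = list(max_k = 40L), eval = list(mode = "per_image", k = 3L),
    seed = seed)))
  m <- merge(res$report, bio$truth, by = "protein_id")
  list(balanced = mean(c(mean(m$is_biomarker.x[m$is_biomarker.y]),
                         mean(!m$is_biomarker.x[!m$is_biomarker.y]))),
       sensitivity = mean(m$is_biomarker.x[m$is_biomarker.y]),
       loc_normal = mean(m$normal_loc == m$normal_class),
       loc_cancer = mean(m$cancer_loc == m$cancer_class),
       cv_accuracy = res$cv_report$accuracy,
       run = res, merged = m, dir = mdir)
}
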