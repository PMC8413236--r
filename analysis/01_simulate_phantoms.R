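#!/usr/bin/env Rscript
# Simulate CT lung phantoms with known pleural PPFE coverage.
#
# Writes: results/phantoms/phantom_<id>.nii.gz (HU volumes),
#         results/phantoms/sidecars.csv (carina + radiologist presence),
#         results/phantoms/truth.json (exact voxel-counted ground truth).

suppressPackageStartupMessages(library(ppfequant))
seed <- 20240901L
out_dir <- "results/phantoms"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

coverages <- c(0, 0, 5, 10, 15, 20, 25, 30, 35, 40)
truth <- list()
sidecars <- data.frame()
for (i in seq_along(coverages)) {
  id <- sprintf("phantom_%02d", i)
  spec <- phantom_with_coverage(phantom_spec(seed = seed + i), coverages[i])
  ph <- generate_phantom(spec)
  write_ct_nifti(ph$volume, file.path(out_dir, paste0(id, ".nii.gz")))
  truth[[id]] <- list(requested_coverage = coverages[i],
                      true_cppfe_percent = ph$truth$true_cppfe_percent,
                      shell_voxels = ph$truth$shell_voxels_total,
                      dense_voxels = ph$truth$dense_shell_voxels_total,
                      bifurcation_slice = spec$bifurcation_slice,
                      seed = spec$seed)
  sidecars <- rbind(sidecars, data.frame(
    id = id, vppfe_present = coverages[i] > 0,
    carina_slice = NA_integer_))
  cat(sprintf("%s: requested %2.0f%%, counted truth %5.2f%%\n",
              id, coverages[i], ph$truth$true_cppfe_percent))
}
write.csv(sidecars, file.path(out_dir, "sidecars.csv"), row.names = FALSE)
jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                     auto_unbox = TRUE, digits = NA)
cat("Phantom set written to", out_dir, "\n")
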