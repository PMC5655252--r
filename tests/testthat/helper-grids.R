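# shared grids and tiny datasets for the test suite

# coarse 4 mm box grid for fast unit tests
tiny_grid <- function(half_mm = 36, voxel_mm = 4) {
  brain_grid(voxel_mm = voxel_mm,
             bbox = cbind(rep(-half_mm, 3), rep(half_mm, 3)), mask = "all")
}

# reduced 2 mm spherical mask used for pipeline-scale simulations
recovery_grid <- function() {
  g0 <- brain_grid(voxel_mm = 2, bbox = cbind(rep(-36, 3), rep(36, 3)),
                   mask = "all")
  m <- gm_ellipsoid_mask(g0, center = c(0, 0, 0), semiaxes = c(34, 34, 34))
  brain_grid(voxel_mm = 2, bbox = cbind(rep(-36, 3), rep(36, 3)), mask = m)
}

fixture_studies <- function() load_study_table(sdmeta_example_studies())

# empty peak set for every study in a table (encodes "no peaks reported")
no_peaks <- function(studies) {
  d <- data.frame(study_id = character(), x = numeric(), y = numeric(),
                  z = numeric(), space = character(), direction = character(),
                  stat_type = character(), stat_value = numeric())
  f <- tempfile(fileext = ".tsv")
  utils::write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  load_peak_tables(f, studies)
}

# hand-written peak TSV helper
write_peaks_tsv <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  f
}
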