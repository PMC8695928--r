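# Programmatic fixtures: no data files, everything built from seeds.

flat_map <- function(value, modality = "FE", laterality = "OD") {
  topography_map(matrix(value, 121, 121), modality, laterality)
}

# random elevation-style map (unrestricted sign, no validation warnings)
random_map <- function(seed, laterality = "OD", modality = "FE", sd = 10) {
  set.seed(seed)
  topography_map(matrix(rnorm(121^2, sd = sd), 121, 121), modality, laterality)
}

# paired random exams over the four differential modalities
random_exam_pair <- function(seed) {
  set.seed(seed)
  mk <- function(lat) {
    vals <- list(FK = matrix(rnorm(121^2, 43, 1), 121, 121),
                 FE = matrix(rnorm(121^2, 0, 10), 121, 121),
                 BE = matrix(rnorm(121^2, 0, 15), 121, 121),
                 CP = matrix(rnorm(121^2, 540, 20), 121, 121))
    maps <- lapply(names(vals), function(m) topography_map(vals[[m]], m, lat))
    names(maps) <- names(vals)
    eye_exam(paste0("rnd", seed), lat, maps)
  }
  list(od = mk("OD"), os = mk("OS"))
}

# relabel an exam's laterality (for eye-swap symmetry checks)
relabel_exam <- function(exam, laterality) {
  maps <- lapply(exam$maps, function(m) {
    topography_map(m$values, m$modality, laterality)
  })
  eye_exam(exam$subject_id, laterality, maps)
}

# straightforward re-implementation of the differential summaries:
# explicit flip, cellwise subtraction, loop over zone cells
naive_triplet <- function(os_vals, od_vals, radius_mm = 1.5,
                          spacing_mm = 0.1) {
  flip <- matrix(NA_real_, 121, 121)
  for (i in 1:121) for (j in 1:121) flip[i, j] <- od_vals[i, 122 - j]
  d <- abs(os_vals - flip)
  cells <- c()
  for (di in -60:60) for (dj in -60:60) {
    if (spacing_mm * sqrt(di^2 + dj^2) <= radius_mm + 1e-9)
      cells <- c(cells, d[61 + di, 61 + dj])
  }
  m <- mean(cells)
  c(max = max(cells), mean = m, sd = sqrt(sum((cells - m)^2) / length(cells)))
}

zero_asym_profile <- function(seed = 1, base = cornea_profile()) {
  pair_profile(base = base,
               jitter = c(R_ant = 0, R_post = 0, CCT = 0, astig_D = 0,
                          astig_axis = 0, Q = 0),
               noise_sd = c(FK = 0, FE = 0, BE = 0, CP = 0),
               seed = seed)
}
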