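# build a small on-disk synthetic study: n vessels x n days
write_mini_study <- function(dir, coh, n_lines = 512L, seed0 = 100L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obs <- coh$observations
  rows <- lapply(seq_len(nrow(obs)), function(i) {
    o <- obs[i, ]
    if (is.na(o$diameter_um)) return(NULL)
    kpath <- file.path(dir, sprintf("%s_d%d.tif", o$vessel_id, o$day))
    vel <- if (is.na(o$velocity_mm_s)) 1 else o$velocity_mm_s
    ky <- generate_kymograph(kymograph_truth(velocity = vel,
                                             n_lines = n_lines,
                                             noise_sd = 0.08,
                                             seed = seed0 + i))
    write_kymograph_tiff(ky, kpath)
    ppath <- file.path(dir, sprintf("%s_d%d_profile.csv", o$vessel_id, o$day))
    pr <- generate_profile(o$diameter_um, pixel_size = 0.5,
                           shape = "tophat", noise_sd = 0.04,
                           seed = seed0 + i)
    write.csv(data.frame(intensity = pr$intensity, pixel_size_um = 0.5),
              ppath, row.names = FALSE)
    data.frame(vessel_id = o$vessel_id, age_day = o$age_day,
               session_day = o$day, kymograph_path = kpath,
               profile_path = ppath, line_rate_hz = 2000,
               pixel_size_um = 0.5, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
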