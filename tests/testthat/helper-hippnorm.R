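# Fixtures are built in code at test time; nothing binary is stored.

# Write a synthetic FreeSurfer-dialect aseg.stats file and return its path.
write_aseg_fixture <- function(left = 3500.0, right = 3621.5, etiv = 1450000.5,
                               n_distractors = 0, drop_etiv = FALSE,
                               drop_left = FALSE) {
  path <- withr::local_tempfile(fileext = ".stats",
                                .local_envir = parent.frame())
  lines <- c(
    "# Title Segmentation Statistics",
    "# subjectname synthetic",
    "# Measure BrainSeg, BrainSegVol, Brain Segmentation Volume, 1150000.0, mm^3",
    if (!drop_etiv) {
      sprintf("# Measure EstimatedTotalIntraCranialVol, eTIV, Estimated Total Intracranial Volume, %f, mm^3", etiv)
    },
    "# ColHeaders Index SegId NVoxels Volume_mm3 StructName normMean normStdDev normMin normMax normRange"
  )
  seg_row <- function(idx, segid, vol, name) {
    sprintf(" %2d %3d %6d %10.1f %-28s %7.1f %6.1f %5.0f %5.0f %5.0f",
            idx, segid, round(vol), vol, name, 80, 10, 20, 120, 100)
  }
  body <- character(0)
  if (!drop_left) body <- c(body, seg_row(1, 17, left, "Left-Hippocampus"))
  body <- c(body, seg_row(2, 53, right, "Right-Hippocampus"))
  if (n_distractors > 0) {
    body <- c(body, vapply(seq_len(n_distractors), function(i) {
      seg_row(2 + i, 100 + i, 1000 + 13 * i, sprintf("Synthetic-Region-%02d", i))
    }, character(1)))
  }
  writeLines(c(lines, body), path)
  path
}

# Write a small cohort CSV from a data frame and return its path.
write_cohort_fixture <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path, na = "")
  path
}

# A well-formed 3-row cohort data frame.
cohort_rows <- function() {
  data.frame(
    subject_id = c("A1", "A2", "A3"),
    age = c(62, 75.5, 88),
    sex = c("F", "M", "F"),
    diagnosis = c("CN", "MCI", "AD"),
    tool = "FS",
    left_hv = c(3600, 3200, 2800),
    right_hv = c(3700, 3310, 2905),
    tiv_value = c(1380, 1500, 1420)
  )
}

# FS-like generating configuration at the reference study scale.
fs_config <- function(seed, n = 532, ...) {
  generator_config(seed = seed, n_cn = n, ...)
}

# AA-like generating configuration: logistic residuals, log-scale location.
aa_config <- function(seed, n = 421, ...) {
  generator_config(seed = seed, n_cn = n, family = "logistic",
                   location_link = "log",
                   beta0 = log(5000) + 0.004 * 74, beta_age = -0.004,
                   dispersion = 0.11 * sqrt(3) / pi,
                   group_shift = c(CN = 0, MCI = -380, AD = -913),
                   right_offset = 100, tool = "AA", ...)
}

# Fit an FS-like normative model on a fresh synthetic cohort.
fitted_fs_model <- function(seed = 7, n = 532) {
  cohort <- normalize_cohort(generate_cohort(fs_config(seed, n)))
  fit_normative(cohort, "gamma", volume_col = "left_hv_norm",
                tool = "FS", hemisphere = "left")
}
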