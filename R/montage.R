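#' The 19-channel 10-20 scalp montage
#'
#' Channel labels of the standard 19-electrode 10-20 layout used throughout
#' the package, in a fixed order (frontal to occipital).
#'
#' @return Character vector of 19 channel labels.
#' @export
eeg_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "O2")
}

# Spatial gain of the background alpha rhythm: occipital-dominant, fading
# towards frontal sites.
alpha_gain_map <- function() {
  g <- c(Fp1 = 0.15, Fp2 = 0.15, F7 = 0.2, F3 = 0.2, Fz = 0.2, F4 = 0.2,
         F8 = 0.2, T3 = 0.35, C3 = 0.4, Cz = 0.4, C4 = 0.4, T4 = 0.35,
         T5 = 0.5, P3 = 0.7, Pz = 0.7, P4 = 0.7, T6 = 0.5,
         O1 = 1.0, O2 = 1.0)
  g[eeg_channels()]
}

# Spatial attenuation of the class-dependent evoked component: full amplitude
# at O1/O2, half at parietal/central midline, 0.4 at Fz, 0.2 elsewhere.
evoked_gain_map <- function() {
  g <- stats::setNames(rep(0.2, 19L), eeg_channels())
  g[c("O1", "O2")] <- 1.0
  g[c("P3", "P4", "Pz", "Cz")] <- 0.5
  g["Fz"] <- 0.4
  g[eeg_channels()]
}

# Volume-conduction gains of the ocular sources onto scalp channels:
# strongest at the frontal pole, negligible occipitally.
default_eog_gains <- function() {
  g <- c(Fp1 = 0.5, Fp2 = 0.5, F7 = 0.3, F3 = 0.3, Fz = 0.3, F4 = 0.3,
         F8 = 0.3, T3 = 0.15, C3 = 0.15, Cz = 0.15, C4 = 0.15, T4 = 0.15,
         T5 = 0.08, P3 = 0.08, Pz = 0.08, P4 = 0.08, T6 = 0.08,
         O1 = 0.04, O2 = 0.04)
  g[eeg_channels()]
}
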