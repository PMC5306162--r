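# ---------------------------------------------------------------------------
# Published reference tables for a 16-artery probabilistic cerebral
# atlas built from 167 population-based subjects, with a rigid-body
# comparison atlas and a 10-patient clinical labeling sample.  These
# per-artery values are the inputs for the aggregate statistics
# (whole-atlas AVR, column means, signed-rank and rank-correlation
# comparisons) and serve as regression fixtures for the metric
# functions.
# ---------------------------------------------------------------------------

#' Reference per-artery atlas characterization table
#'
#' Per-artery characterization of a published 16-artery probabilistic
#' cerebral atlas (non-linear normalization, `_nl` columns) and its
#' rigid-body counterpart (`_rb` columns): number of included arteries,
#' mean per-subject artery volume, concatenated volume, arterial volume
#' ratio (AVR), dominating volume and maximum probability.
#'
#' @return A data frame with one row per artery.
#' @export
reference_atlas_metrics <- function() {
  df <- read.csv(text = "
artery,n_arteries,pct_subjects,mean_volume_cm3,sd_volume_cm3,conc_nl,conc_rb,avr_nl,avr_rb,dom_nl,dom_rb,maxp_nl,maxp_rb
ica_right,167,100,3.0,0.43,19.5,51.0,6.4,16.8,97.6,95.5,1.0,0.47
ica_left,167,100,3.0,0.52,19.8,45.8,6.7,15.5,97.1,95.2,1.0,0.53
ba,166,99.4,0.52,0.18,9.9,18.7,19.0,35.7,72.5,73.1,0.79,0.25
va_right,153,91.6,0.70,0.43,18.3,36.4,26.1,52.0,95.4,95.2,0.51,0.12
va_left,154,92.2,0.83,0.41,19.2,39.7,23.2,48.0,91.8,93.5,0.68,0.15
pca_right,166,99.4,0.29,0.13,6.4,14.2,22.0,48.1,88.4,79.6,0.54,0.14
pca_left,165,98.8,0.28,0.14,6.2,13.0,21.9,46.1,89.6,82.7,0.58,0.15
mca_right,167,100,0.46,0.12,5.8,15.9,12.6,34.8,81.9,79.0,0.90,0.20
mca_left,167,100,0.44,0.13,6.5,16.3,14.8,37.1,81.6,78.2,0.89,0.18
aca_right,157,94.0,0.24,0.074,2.9,9.4,11.8,39.0,75.0,59.8,0.85,0.16
aca_left,162,97.0,0.25,0.078,2.5,9.2,10.0,36.4,64.4,50.9,0.83,0.18
aca_distal,167,100,0.59,0.27,10.7,21.5,18.2,36.6,95.9,93.8,0.66,0.22
pcoa_right,50,29.9,0.17,0.060,2.4,4.5,13.9,26.1,69.0,38.8,0.88,0.24
pcoa_left,30,17.9,0.19,0.065,1.7,3.5,9.1,18.8,77.4,42.8,0.90,0.23
mca_distal_right,162,97.0,0.40,0.25,14.8,24.4,36.8,61.0,97.7,96.9,0.31,0.15
mca_distal_left,160,95.8,0.29,0.20,12.5,18.3,42.8,62.8,97.9,97.4,0.29,0.11
", strip.white = TRUE)
  df
}

#' Reference leave-one-out validation table
#'
#' Per-artery outcome counts over 167 leave-one-out labeled subjects:
#' true positives (correctly identified existing), true negatives
#' (correctly identified non-existing), false positives (mislabeled
#' non-existing), and the three false-negative kinds (mislabeled
#' existing, not identified, too short), with the published
#' sensitivity, specificity and accuracy percentages.  The counts of
#' the two vertebral-artery rows cannot be recovered unambiguously
#' from the published layout and are `NA`; their accuracy column is
#' retained.
#'
#' @return A data frame with one row per artery.
#' @export
reference_loo_counts <- function() {
  df <- read.csv(text = "
artery,tp,tn,fp,fn_mislabeled,fn_not_identified,fn_too_short,sensitivity,specificity,accuracy
ica_right,165,0,0,2,0,0,99,NA,99
ica_left,167,0,0,0,0,0,100,NA,100
ba,163,0,1,2,1,0,98,0,98
va_right,NA,NA,NA,NA,NA,NA,NA,NA,84
va_left,NA,NA,NA,NA,NA,NA,NA,NA,92
pca_right,165,1,0,0,0,1,99,100,99
pca_left,163,2,0,0,0,2,99,100,99
mca_right,167,0,0,0,0,0,100,NA,100
mca_left,167,0,0,0,0,0,100,NA,100
aca_right,154,9,1,0,3,0,98,90,98
aca_left,160,5,0,0,2,0,99,100,99
aca_distal,167,0,0,0,0,0,100,NA,100
pcoa_right,43,112,5,0,7,0,86,96,93
pcoa_left,26,124,13,0,4,0,87,91,90
mca_distal_right,160,2,3,0,0,2,99,40,97
mca_distal_left,142,3,4,0,5,13,89,43,86
", strip.white = TRUE)
  df
}

#' Reference clinical validation table
#'
#' Per-artery outcome counts for atlas-based labeling of a 10-patient
#' clinical sample (transient ischemic attack or lacunar infarct), with
#' the published sensitivity, specificity and accuracy.
#'
#' @return A data frame with one row per artery.
#' @export
reference_clinical_counts <- function() {
  df <- read.csv(text = "
artery,tp,tn,fn_not_identified,fn_too_short,sensitivity,specificity,accuracy
ica_right,10,0,0,0,100,NA,100
ica_left,10,0,0,0,100,NA,100
ba,10,0,0,0,100,NA,100
va_right,8,0,0,2,80,NA,80
va_left,10,0,0,0,100,NA,100
pca_right,8,0,0,2,80,NA,80
pca_left,10,0,0,0,100,NA,100
mca_right,10,0,0,0,100,NA,100
mca_left,10,0,0,0,100,NA,100
aca_right,10,0,0,0,100,NA,100
aca_left,10,0,0,0,100,NA,100
aca_distal,9,0,1,0,90,NA,90
pcoa_right,0,7,3,0,0,100,70
pcoa_left,0,8,2,0,0,100,80
mca_distal_right,9,0,1,0,90,NA,90
mca_distal_left,9,0,1,0,90,NA,90
", strip.white = TRUE)
  df
}
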