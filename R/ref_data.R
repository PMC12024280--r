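# Bundled reference tables from a published 63-family P. vannamei meat-yield
# experiment (899 genotyped animals, ~9.2k post-QC SNPs). They serve as the
# stated world the simulator emulates and as inputs to arithmetic checks;
# none of them is produced by this package's computations.

ref_path <- function(file) {
  system.file("extdata", file, package = "mtgblup", mustWork = TRUE)
}

#' Reference tank survival records
#'
#' Stocking and harvest counts of the six concrete tanks (two light-intensity
#' groups of three tanks) in the reference 63-family shrimp experiment.
#'
#' @return Tibble: tank, group, families, stocked, harvested.
#' @export
ref_survival <- function() {
  readr::read_tsv(ref_path("tank_survival.tsv"), show_col_types = FALSE)
}

#' Reference cross-validation accuracies and biases
#'
#' Published genomic prediction accuracy and bias of the single-trait
#' baseline (STGM) and the two-trait models under CV1/CV2 for the meat-yield
#' (MY) and net-meat-weight (MW) targets in the reference experiment.
#'
#' @return Tibble: target, model, strategy, accuracy, bias.
#' @export
ref_cv_accuracy <- function() {
  readr::read_tsv(ref_path("cv_accuracy_reference.tsv"), show_col_types = FALSE)
}

#' Reference genetic parameter estimates
#'
#' Published single-trait heritabilities and two-trait genetic correlations
#' (with standard errors) for MY, MW, BW, BL and AL in the reference
#' experiment.
#'
#' @return Tibble: parameter, trait_x, trait_y, estimate, se.
#' @export
ref_genetic_params <- function() {
  readr::read_tsv(ref_path("genetic_params_reference.tsv"),
                  show_col_types = FALSE, na = "NA")
}
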