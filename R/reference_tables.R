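#' Published NTP two-year bioassay liver-tumor calls for the 26 chemicals
#'
#' The mouse liver adenoma/carcinoma calls (at a one-sided p = 0.01
#' threshold) for the 26 NTP-tested chemicals in the 90-day study design,
#' with the reported borderline p-values for the two equivocal chemicals.
#'
#' @return data frame: `chemical`, `short_name`, `liver_tumor_call`
#'   (`Yes`/`No`/`Eq`), `p_reported` (`NA` except equivocals).
#' @export
mouse_liver_calls <- function() {
  utils::read.delim(system.file("extdata", "ntp_mouse_liver_calls.tsv",
                                package = "carcinopath"),
                    stringsAsFactors = FALSE)
}

#' Human liver-cancer risk-factor panel with carcinogenicity labels
#'
#' The expression data sets associated with liver-cancer risk factors
#' (hepatitis C, diabetes, cirrhosis) are labeled positive, as is the
#' liver-cancer gene-polymorphism set; polymorphism sets for other cancers
#' and for Alzheimer's disease and schizophrenia are negative.
#'
#' @return data frame: `id`, `group` (`expression`/`polymorphism`),
#'   `risk_factor`, `label`.
#' @export
human_risk_panel <- function() {
  utils::read.delim(system.file("extdata", "human_liver_risk_panel.tsv",
                                package = "carcinopath"),
                    stringsAsFactors = FALSE)
}

#' Published false-positive/false-negative lists of the reference predictor
#'
#' The confusion lists reported for the pathway-based predictor at
#' operating points with specificity between 56 and 75 percent, for the
#' mouse (within-species) and human (extrapolated) panels.
#'
#' @return data frame: `species`, `type`
#'   (`false_positive`/`false_negative`), `id`.
#' @export
reference_confusion_lists <- function() {
  utils::read.delim(system.file("extdata", "reference_confusion_lists.tsv",
                                package = "carcinopath"),
                    stringsAsFactors = FALSE)
}

#' Mouse chemical labels at the p = 0.01 call convention
#'
#' @return named character vector (short name -> `"positive"`/
#'   `"negative"`); equivocal bioassay outcomes count as negative.
#' @export
mouse_chemical_labels <- function() {
  calls <- mouse_liver_calls()
  stats::setNames(ifelse(calls$liver_tumor_call == "Yes",
                         "positive", "negative"),
                  calls$short_name)
}

# Solve for the treated tumor proportion that gives a target pooled
# two-proportion z with fixed arm sizes and control proportion.
solve_p_treat <- function(z_target, n = 50, p_cont = 0.15) {
  stats::uniroot(function(p_t) {
    poly3_z(bioassay_record("tmp", n, p_t, n, p_cont)) - z_target
  }, interval = c(p_cont, 1 - 1e-9), tol = 1e-12)$root
}

#' Synthetic bioassay records reproducing the published mouse calls
#'
#' Constructs one synthetic [bioassay_record()] per chemical whose poly-3
#' statistic matches its published call: clearly significant for tumor
#' positives, the reported borderline one-sided p for the two equivocals,
#' and non-significant for negatives. Used to verify that the p = 0.01
#' call rule reproduces the published 10 positive / 16 negative split.
#'
#' @param n animals per synthetic arm (default 50).
#' @param p_cont control tumor proportion (default 0.15).
#' @return named list of [bioassay_record()]s keyed by short name.
#' @export
mouse_call_records <- function(n = 50, p_cont = 0.15) {
  calls <- mouse_liver_calls()
  z_for <- function(call, p_rep) {
    switch(call,
           Yes = 3.5,
           Eq = stats::qnorm(1 - p_rep),
           No = 0.5)
  }
  recs <- lapply(seq_len(nrow(calls)), function(i) {
    z <- z_for(calls$liver_tumor_call[i], calls$p_reported[i])
    bioassay_record(calls$short_name[i], n,
                    solve_p_treat(z, n = n, p_cont = p_cont), n, p_cont)
  })
  stats::setNames(recs, calls$short_name)
}
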