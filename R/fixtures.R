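#' Reference activity table: 41 stilbene-derived LSD1 inhibitors
#'
#' The embedded activity/prediction table of the reference series, exactly
#' as printed: compound id, IC50 (uM), pIC50, the CoMFA and CoMSIA
#' predictions with residuals, the assigned binding-mode category, and the
#' test-set flag (9 of 41 compounds, 22%).
#'
#' One printed cell is internally inconsistent: compound 33's IC50
#' (1.93 uM) does not back-convert to its pIC50 (5.888, which corresponds
#' to 1.294 uM); the pIC50 agrees exactly with the printed prediction plus
#' residual and is the value used everywhere downstream.  The row is kept
#' verbatim and the inconsistency is flagged by [reproduce_paper()].
#'
#' @return Data frame with 41 rows.
#' @export
fixture_table1 <- function() {
  path <- system.file("extdata", "lsd1_stilbene_activities.csv",
                      package = "qsar3d", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = ",",
                    stringsAsFactors = FALSE,
                    colClasses = c(compound_id = "character"))
}

#' Reference external-validation table (printed thresholds and values)
#'
#' The printed external-validation battery for the final CoMFA and CoMSIA
#' models: per-condition parameter, threshold, and the two printed values.
#'
#' @return Data frame with one row per condition.
#' @export
fixture_table3 <- function() {
  data.frame(
    condition = c("1", "2a", "2b", "3a", "3b", "4a", "4b", "5", "6"),
    parameter = c("R2", "R0^2", "R'0^2", "k", "k'",
                  "(R2-R0^2)/R2", "(R2-R'0^2)/R2", "|R0^2-R'0^2|", "rm2"),
    threshold = c(">0.6", "close to R2", "close to R2",
                  "0.85<k<1.15", "0.85<k'<1.15", "<0.1", "<0.1",
                  "<0.3", ">0.5"),
    comfa = c(0.855, 0.851, 0.847, 1.001, 0.998, 0.005, 0.009, 0.004,
              0.799),
    comsia = c(0.861, 0.857, 0.755, 0.983, 1.010, 0.005, 0.123, 0.102,
               0.804),
    stringsAsFactors = FALSE)
}

#' Reference MM/GBSA component table (four LSD1 complexes)
#'
#' Binding free-energy components of the four simulated ligand-LSD1
#' complexes, exactly as printed (kcal/mol), including the printed
#' solvation and binding totals used for consistency checks.
#'
#' @return Data frame with 4 rows.
#' @export
fixture_table7 <- function() {
  path <- system.file("extdata", "lsd1_gbsa_components.csv",
                      package = "qsar3d", mustWork = TRUE)
  read_component_table(path)
}

#' The reference dataset as a qsar_dataset
#'
#' @return A [qsar_dataset()] built from [fixture_table1()] (consistency
#'   warnings suppressed for the one flagged row).
#' @export
fixture_dataset <- function() {
  qsar_dataset(fixture_table1(), check_consistency = FALSE)
}
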