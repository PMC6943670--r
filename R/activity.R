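#' Percent inhibition from a fluorescence/absorbance pair
#'
#' In the coupled demethylase assay the signal of an uninhibited control well
#' is compared with the signal in the presence of inhibitor; inhibition is the
#' fractional signal loss expressed as a percentage,
#' \code{100 * (control - sample) / control}.
#'
#' @param control Signal of the uninhibited control well (arbitrary units,
#'   must be > 0).
#' @param sample Signal of the inhibited well (same units, >= 0).
#' @return Percent inhibition; negative when the sample signal exceeds the
#'   control.
#' @examples
#' inhibition_percent(80, 20)  # 75
#' @export
inhibition_percent <- function(control, sample) {
  if (!is.numeric(control) || !is.numeric(sample))
    stop("'control' and 'sample' must be numeric")
  if (any(!is.finite(control)) || any(!is.finite(sample)))
    stop("invalid measurement: non-finite signal")
  if (any(control <= 0))
    stop("invalid measurement: control signal must be positive")
  if (any(sample < 0))
    stop("invalid measurement: sample signal must be non-negative")
  100 * (control - sample) / control
}

#' Convert IC50 in micromolar to pIC50
#'
#' pIC50 is the negative decadic logarithm of the molar IC50, so an IC50
#' given in uM maps to \code{-log10(ic50_um * 1e-6) = 6 - log10(ic50_um)}.
#' The convention (molar log, uM input) is fixed by the reference series,
#' where 0.121 uM corresponds to pIC50 6.917.
#'
#' @param ic50_um IC50 value(s) in micromolar; must be positive.
#' @return pIC50 value(s).
#' @examples
#' pic50_from_ic50(1)      # 6
#' pic50_from_ic50(0.121)  # 6.917
#' @export
pic50_from_ic50 <- function(ic50_um) {
  if (!is.numeric(ic50_um)) stop("'ic50_um' must be numeric")
  if (any(!is.finite(ic50_um)) || any(ic50_um <= 0))
    stop("IC50 must be a positive finite value (uM)")
  -log10(ic50_um * 1e-6)
}

#' Assemble a QSAR dataset from activity records
#'
#' @param records Data frame with columns \code{compound_id}, at least one of
#'   \code{ic50_uM} / \code{pic50}, and a logical \code{is_test} column.
#'   A missing \code{pic50} is filled from \code{ic50_uM}.
#' @param structures Optional named list of [compound_structure()] objects;
#'   every name must appear in \code{records$compound_id}.
#' @param check_consistency Verify that records carrying both an IC50 and a
#'   pIC50 agree within \code{5e-4} (warning if not).
#' @return An object of class \code{qsar_dataset}.
#' @export
qsar_dataset <- function(records, structures = NULL, check_consistency = TRUE) {
  stopifnot(is.data.frame(records))
  if (!"compound_id" %in% names(records))
    stop("records must have a 'compound_id' column")
  records$compound_id <- as.character(records$compound_id)
  if (anyDuplicated(records$compound_id))
    stop("duplicate compound ids: ",
         paste(unique(records$compound_id[duplicated(records$compound_id)]),
               collapse = ", "))
  if (!"pic50" %in% names(records)) records$pic50 <- NA_real_
  if (!"ic50_uM" %in% names(records)) records$ic50_uM <- NA_real_
  fill <- is.na(records$pic50) & !is.na(records$ic50_uM)
  records$pic50[fill] <- pic50_from_ic50(records$ic50_uM[fill])
  if (any(is.na(records$pic50)))
    stop("records without either pic50 or ic50_uM: ",
         paste(records$compound_id[is.na(records$pic50)], collapse = ", "))
  if (!"is_test" %in% names(records)) records$is_test <- FALSE
  records$is_test <- as.logical(records$is_test)
  if (check_consistency) {
    both <- !is.na(records$ic50_uM)
    dev <- abs(pic50_from_ic50(records$ic50_uM[both]) - records$pic50[both])
    if (any(dev > 5e-4))
      warning("pic50 inconsistent with ic50_uM (>5e-4) for: ",
              paste(records$compound_id[both][dev > 5e-4], collapse = ", "))
  }
  if (!is.null(structures)) {
    if (is.null(names(structures)) || any(!nzchar(names(structures))))
      structures <- setNames(structures,
                             vapply(structures, `[[`, "", "compound_id"))
    unknown <- setdiff(names(structures), records$compound_id)
    if (length(unknown))
      stop("structures without an activity record: ",
           paste(unknown, collapse = ", "))
  }
  structure(list(records = records, structures = structures),
            class = "qsar_dataset")
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat(sprintf("qsar_dataset: %d compounds (%d test), %d structures\n",
              nrow(x$records), sum(x$records$is_test),
              length(x$structures)))
  invisible(x)
}

#' Read an activity table
#'
#' Delimited text with a header; comma or tab separation is auto-detected.
#' Expected columns: \code{compound_id}, \code{ic50_uM} and/or \code{pic50},
#' and a logical \code{is_test} flag (absent flag means all-training).
#'
#' @param path Path to the file.
#' @param ... Passed on to [qsar_dataset()].
#' @return A \code{qsar_dataset}.
#' @export
read_activity_table <- function(path, ...) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = c(compound_id = "character"))
  qsar_dataset(df, ...)
}

#' Write an activity table as CSV
#'
#' @param ds A \code{qsar_dataset} or a plain records data frame.
#' @param path Output path.
#' @export
write_activity_table <- function(ds, path) {
  df <- if (inherits(ds, "qsar_dataset")) ds$records else ds
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a train/test split from a dataset's test flags
#'
#' @param ds A \code{qsar_dataset}.
#' @return List with \code{train_ids}, \code{test_ids} and
#'   \code{train_mean_pic50} (the training-set mean used as the reference
#'   activity in external-validation sums of squares).
#' @export
data_split <- function(ds) {
  stopifnot(inherits(ds, "qsar_dataset"))
  r <- ds$records
  list(train_ids = r$compound_id[!r$is_test],
       test_ids = r$compound_id[r$is_test],
       train_mean_pic50 = mean(r$pic50[!r$is_test]))
}

#' Validate a train/test split against the series-design rules
#'
#' Checks, without mutating anything: (i) activity containment -- the test
#' set's pIC50 range must lie inside the training range (max(test) <=
#' max(train), min(test) >= min(train)); (ii) the test fraction must be
#' within 20--25% of the dataset; (iii) train and test are disjoint and
#' together cover the dataset.
#'
#' @param ds A \code{qsar_dataset}.
#' @param split Optional split as returned by [data_split()]; defaults to the
#'   dataset's own test flags.
#' @return List of per-rule results plus an overall \code{pass} flag and the
#'   actual test fraction.
#' @export
validate_split <- function(ds, split = data_split(ds)) {
  stopifnot(inherits(ds, "qsar_dataset"))
  r <- ds$records
  ids <- r$compound_id
  unknown <- setdiff(c(split$train_ids, split$test_ids), ids)
  if (length(unknown))
    stop("split refers to unknown compound ids: ",
         paste(unknown, collapse = ", "))
  disjoint <- length(intersect(split$train_ids, split$test_ids)) == 0
  covered <- setequal(union(split$train_ids, split$test_ids), ids)
  ytr <- r$pic50[match(split$train_ids, ids)]
  yte <- r$pic50[match(split$test_ids, ids)]
  containment <- length(yte) > 0 && length(ytr) > 0 &&
    max(yte) <= max(ytr) && min(yte) >= min(ytr)
  frac <- length(split$test_ids) / nrow(r)
  frac_ok <- frac >= 0.20 && frac <= 0.25
  list(containment = containment,
       fraction = frac,
       fraction_ok = frac_ok,
       disjoint = disjoint,
       covered = covered,
       pass = containment && frac_ok && disjoint && covered)
}
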