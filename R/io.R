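#' Write a synthetic dataset to plain-text files
#'
#' Emits four files into `dir`: `plate.csv` (wide sample x analyte MFI
#' table; the first data row, keyed `.analyte_role`, carries the analyte
#' roles), `clinical.csv`, `edges.tsv` (whitespace-delimited
#' `protein1 protein2 combined_score` in the fractional 0-1 dialect) and
#' `truth.json`.  All four round-trip losslessly through the module's
#' readers.
#'
#' @param ds an `sba_dataset` from [simulate_bead_array()].
#' @param dir output directory (created, recursively, if missing).
#' @param overwrite overwrite existing files?  Defaults to `FALSE`, in
#'   which case a collision is an error.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(ds, dir, overwrite = FALSE) {
  stopifnot(inherits(ds, "sba_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("plate.csv", "clinical.csv", "edges.tsv",
                            "truth.json"))
  names(paths) <- c("plate", "clinical", "edges", "truth")
  if (!overwrite && any(file.exists(paths))) {
    stop("refusing to overwrite existing files in ", dir,
         " (use overwrite = TRUE)", call. = FALSE)
  }

  pl <- ds$plate
  wide <- data.frame(sample_id = c(".analyte_role", rownames(pl$mfi)),
                     well_role = c("", unname(pl$well_role)),
                     stringsAsFactors = FALSE, check.names = FALSE)
  for (an in colnames(pl$mfi)) {
    wide[[an]] <- c(unname(pl$analyte_role[an]), format(pl$mfi[, an],
                                                        trim = TRUE))
  }
  utils::write.csv(wide, paths["plate"], row.names = FALSE, quote = FALSE)

  utils::write.csv(ds$clinical, paths["clinical"], row.names = FALSE,
                   quote = FALSE)

  ed <- igraph::as_data_frame(ds$graph, what = "edges")
  ed <- data.frame(protein1 = ed$from, protein2 = ed$to,
                   combined_score = format(ed$strength, digits = 17,
                                           trim = TRUE, scientific = FALSE))
  utils::write.table(ed, paths["edges"], sep = " ", row.names = FALSE,
                     quote = FALSE)

  truth <- ds$truth
  truth$config <- NULL  # full config echo in JSON is keyed separately
  truth$config_echo <- unclass(ds$config)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

#' Read a plate CSV
#'
#' Parses the wide plate format written by [write_dataset()]: columns are
#' analytes, rows are wells, with a `.analyte_role` header row and a
#' `well_role` column.
#'
#' @param path plate CSV path.
#' @return An `sba_plate` object (list: `mfi`, `well_role`, `analyte_role`).
#' @export
read_plate <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (raw$sample_id[1] != ".analyte_role") {
    stop("plate file lacks the .analyte_role header row", call. = FALSE)
  }
  roles <- unlist(raw[1, -(1:2)])
  body <- raw[-1, , drop = FALSE]
  mfi <- as.matrix(body[, -(1:2), drop = FALSE])
  storage.mode(mfi) <- "double"
  rownames(mfi) <- body$sample_id
  if (any(mfi < 0, na.rm = TRUE)) stop("negative MFI in plate", call. = FALSE)
  structure(list(
    mfi = mfi,
    well_role = stats::setNames(body$well_role, body$sample_id),
    analyte_role = stats::setNames(unname(roles), colnames(mfi))
  ), class = "sba_plate")
}

#' Read a clinical CSV
#'
#' @param path clinical CSV path; must contain a unique `patient_id` column.
#' @return data.frame with one row per patient.
#' @export
read_clinical <- function(path) {
  clin <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(clin)) {
    stop("clinical table lacks a patient_id column", call. = FALSE)
  }
  if (anyDuplicated(clin$patient_id)) {
    stop("duplicate patient_id in clinical table", call. = FALSE)
  }
  clin
}

#' Read a ground-truth JSON file
#'
#' @param path path to a `truth.json` written by [write_dataset()].
#' @return list of planted ground-truth values.
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @export
print.sba_plate <- function(x, ...) {
  cat(sprintf("Bead-array plate: %d wells (%d empty) x %d analytes (%d antigens)\n",
              nrow(x$mfi), sum(x$well_role == "empty"), ncol(x$mfi),
              sum(x$analyte_role == "antigen")))
  invisible(x)
}
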