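# CSV dialects. One header row, comma-delimited, UTF-8. Column names are a
# fixed contract so that files interchange with other tools unambiguously.

.cols_morphology <- c("specimen_id", "species", "mass_mg", "span_mm",
                      "chord_mm", "area_cm2")
.cols_dynamics <- c("specimen_id", "replicate", "v_d_m_s", "omega_rad_s",
                    "theta_deg")
.cols_perturbation <- c("specimen_id", "species", "kind", "level_index",
                        "m_ratio", "a_ratio", "replicate", "v_d_m_s",
                        "omega_rad_s", "theta_deg", "failed")

.check_schema <- function(x, need, what, file = NULL) {
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(what, " table", if (!is.null(file)) paste0(" '", file, "'"),
         " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

.read_csv <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Read and write the samara CSV dialects
#'
#' Readers enforce the exact column contract and fail with the missing
#' column names; writers emit plain comma-delimited UTF-8 with a header
#' row and no row names.
#'
#' Morphology columns: `specimen_id, species, mass_mg, span_mm, chord_mm,
#' area_cm2`. Dynamics columns: `specimen_id, replicate, v_d_m_s,
#' omega_rad_s, theta_deg`. Perturbation columns add `kind, level_index,
#' m_ratio, a_ratio, failed`.
#'
#' @param file path to a CSV file.
#' @param x data.frame to write.
#' @return Readers return a data.frame; writers return `file` invisibly.
#' @name samara_io
NULL

#' @rdname samara_io
#' @export
read_morphology <- function(file) {
  x <- .read_csv(file)
  .check_schema(x, .cols_morphology, "morphology", file)
  x
}

#' @rdname samara_io
#' @export
read_dynamics <- function(file) {
  x <- .read_csv(file)
  .check_schema(x, .cols_dynamics, "dynamics", file)
  x
}

#' @rdname samara_io
#' @export
read_perturbation <- function(file) {
  x <- .read_csv(file)
  .check_schema(x, .cols_perturbation, "perturbation", file)
  x
}

#' @rdname samara_io
#' @export
write_samara_csv <- function(x, file) {
  stopifnot(is.data.frame(x))
  utils::write.csv(x, file, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(file)
}
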