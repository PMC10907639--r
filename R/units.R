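#' Convert a morphology/dynamics table from field units to SI
#'
#' Field records carry mass in mg, span and chord in mm, plan area in cm^2,
#' and the coning angle in degrees. All internal force computations use SI
#' (kg, m, m^2); angles stay in degrees and are converted to radians only
#' inside trigonometric evaluation. `to_si()` adds SI columns (`m_kg`,
#' `s_m`, `c_m`, `a_m2`) next to the originals; `to_io()` reconstructs the
#' field-unit columns from the SI ones, so `to_io(to_si(x))` round-trips to
#' better than 1e-12 relative.
#'
#' @param x data.frame with any of the columns `mass_mg`, `span_mm`,
#'   `chord_mm`, `area_cm2` (extra columns pass through untouched).
#' @return `x` with SI columns appended (`to_si`) or field-unit columns
#'   rewritten from the SI columns (`to_io`).
#' @seealso [validate_population()]
#' @examples
#' to_si(data.frame(mass_mg = 12, area_cm2 = 2.5))
#' @export
to_si <- function(x) {
  stopifnot(is.data.frame(x))
  conv <- c(mass_mg = 1e-6, span_mm = 1e-3, chord_mm = 1e-3, area_cm2 = 1e-4)
  si <- c(mass_mg = "m_kg", span_mm = "s_m", chord_mm = "c_m",
          area_cm2 = "a_m2")
  for (col in intersect(names(conv), names(x))) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      stop("column '", col, "' is not numeric", call. = FALSE)
    }
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad)) {
      stop("column '", col, "' has non-positive or non-finite values at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    x[[si[[col]]]] <- v * conv[[col]]
  }
  x
}

#' @rdname to_si
#' @export
to_io <- function(x) {
  stopifnot(is.data.frame(x))
  conv <- c(m_kg = 1e6, s_m = 1e3, c_m = 1e3, a_m2 = 1e4)
  io <- c(m_kg = "mass_mg", s_m = "span_mm", c_m = "chord_mm",
          a_m2 = "area_cm2")
  for (col in intersect(names(conv), names(x))) {
    x[[io[[col]]]] <- x[[col]] * conv[[col]]
  }
  x
}

#' Validate a samara morphology table against its geometric invariants
#'
#' Checks every record for strictly positive mass, span, chord and area,
#' chord not exceeding span, and area not exceeding the span-aligned
#' bounding box `chord * span` (a plan silhouette must fit its bounding
#' box). Violations are listed per specimen rather than raised, so a whole
#' field table can be screened in one pass.
#'
#' @param x data.frame with columns `specimen_id`, `mass_mg`, `span_mm`,
#'   `chord_mm`, `area_cm2`.
#' @return An object of class `samara_validation`: list with `n_records`,
#'   `n_passing`, and a data.frame `violations` (columns `specimen_id`,
#'   `rule`). Empty input is flagged via `empty = TRUE`.
#' @examples
#' pop <- data.frame(specimen_id = "a", species = "synthetic",
#'                   mass_mg = 12, span_mm = 30, chord_mm = 9, area_cm2 = 1.6)
#' validate_population(pop)
#' @export
validate_population <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("specimen_id", "mass_mg", "span_mm", "chord_mm", "area_cm2")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  viol <- data.frame(specimen_id = character(0), rule = character(0),
                     stringsAsFactors = FALSE)
  if (nrow(x)) {
    add <- function(idx, rule) {
      if (length(idx)) {
        viol <<- rbind(viol, data.frame(
          specimen_id = as.character(x$specimen_id[idx]), rule = rule,
          stringsAsFactors = FALSE))
      }
    }
    for (col in c("mass_mg", "span_mm", "chord_mm", "area_cm2")) {
      add(which(!is.finite(x[[col]]) | x[[col]] <= 0),
          paste0(col, " not strictly positive"))
    }
    ok <- is.finite(x$chord_mm) & is.finite(x$span_mm) & is.finite(x$area_cm2)
    add(which(ok & x$chord_mm > x$span_mm), "chord exceeds span")
    # area_cm2 -> mm^2 is *100
    add(which(ok & x$area_cm2 * 100 > x$chord_mm * x$span_mm *
                (1 + 1e-12)),
        "area exceeds chord x span bounding box")
  }
  bad_ids <- unique(viol$specimen_id)
  structure(list(
    n_records = nrow(x),
    n_passing = sum(!(as.character(x$specimen_id) %in% bad_ids)),
    violations = viol,
    empty = nrow(x) == 0L
  ), class = "samara_validation")
}

#' @export
print.samara_validation <- function(x, ...) {
  if (x$empty) {
    cat("Population validation: EMPTY input (0 records)\n")
    return(invisible(x))
  }
  cat("Population validation:", x$n_passing, "of", x$n_records,
      "records pass\n")
  if (nrow(x$violations)) {
    cat("Violations:\n")
    for (i in seq_len(nrow(x$violations))) {
      cat("  ", x$violations$specimen_id[i], ": ", x$violations$rule[i],
          "\n", sep = "")
    }
  }
  invisible(x)
}
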