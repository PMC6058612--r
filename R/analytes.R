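#' Define an analyte channel
#'
#' An analyte is extracted from spectra as the summed intensity inside a
#' closed m/z window `[mz_center - tol, mz_center + tol]` (absolute Da
#' tolerance) or `mz_center * (1 +/- tol * 1e-6)` (ppm tolerance).
#'
#' @param name analyte name (e.g. `"salmeterol"`).
#' @param mz_center window center in Da (> 0).
#' @param tol half-width of the extraction window (> 0).
#' @param tol_unit `"da"` (absolute) or `"ppm"`.
#' @param role one of `drug_inhaled`, `drug_iv`, `marker_vessel`,
#'   `marker_alveolar`, `marker_bronchiolar`, `other`.
#' @return An `analyte` object.
#' @export
analyte <- function(name, mz_center, tol = 0.1, tol_unit = c("da", "ppm"),
                    role = c("other", "drug_inhaled", "drug_iv",
                             "marker_vessel", "marker_alveolar",
                             "marker_bronchiolar")) {
  tol_unit <- match.arg(tol_unit)
  role <- match.arg(role)
  if (mz_center <= 0) stop("mz_center must be positive")
  if (tol <= 0) stop("tolerance must be positive")
  structure(list(name = as.character(name), mz_center = as.numeric(mz_center),
                 tol = as.numeric(tol), tol_unit = tol_unit, role = role),
            class = "analyte")
}

#' @export
print.analyte <- function(x, ...) {
  cat("<analyte> ", x$name, ": m/z ", x$mz_center, " +/- ", x$tol, " ",
      x$tol_unit, " (", x$role, ")\n", sep = "")
  invisible(x)
}

#' The m/z window of an analyte
#' @param a an `analyte`.
#' @return numeric length-2: closed window bounds in Da.
#' @export
analyte_window <- function(a) {
  half <- if (a$tol_unit == "ppm") a$mz_center * a$tol * 1e-6 else a$tol
  c(a$mz_center - half, a$mz_center + half)
}

#' Default analyte table for the dual-isotope salmeterol study
#'
#' Salmeterol is observed as its protonated molecule at m/z 416.1 in positive
#' mode. The remaining masses are monoisotopic assumptions, clearly meant to
#' be overridden when instrument-measured exact masses are available:
#' d3-salmeterol at 416.1 + 3 x 1.00628 Da (three 2H-1H substitutions),
#' Heme b as the protonation-free iron-porphyrin ion, and the
#' phosphatidylcholine markers as protonated molecules.
#'
#' @param d3_shift mass shift of the trideuterated isotopologue in Da.
#' @return A list of `analyte` objects keyed by name.
#' @export
default_analytes <- function(d3_shift = 3 * 1.00628) {
  lst <- list(
    analyte("salmeterol", 416.1, role = "drug_inhaled"),
    analyte("d3_salmeterol", 416.1 + d3_shift, role = "drug_iv"),
    analyte("heme_b", 616.177, role = "marker_vessel"),
    analyte("pc_32_0", 734.569, role = "marker_alveolar"),
    analyte("pc_36_4", 782.569, role = "marker_bronchiolar"))
  names(lst) <- vapply(lst, `[[`, character(1), "name")
  lst
}

#' Read an analyte table from CSV or YAML
#'
#' CSV columns: `name, mz, tol, tol_unit, role`; YAML: a sequence of mappings
#' with the same keys. Missing `tol`/`tol_unit`/`role` fall back to 0.1 Da
#' and `"other"`.
#'
#' @param path file path ending in `.csv`, `.yml` or `.yaml`.
#' @return A named list of `analyte` objects.
#' @export
read_analyte_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  rows <- if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  } else if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else stop("unsupported analyte table format: ", ext)
  lst <- lapply(rows, function(r) {
    analyte(r$name, r$mz,
            tol = if (is.null(r$tol) || is.na(r$tol)) 0.1 else r$tol,
            tol_unit = if (is.null(r$tol_unit) || is.na(r$tol_unit)) "da"
                       else r$tol_unit,
            role = if (is.null(r$role) || is.na(r$role)) "other" else r$role)
  })
  names(lst) <- vapply(lst, `[[`, character(1), "name")
  lst
}

#' Write an analyte table to CSV
#' @param analytes named list of `analyte` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_analyte_table <- function(analytes, path) {
  df <- do.call(rbind, lapply(analytes, function(a)
    data.frame(name = a$name, mz = a$mz_center, tol = a$tol,
               tol_unit = a$tol_unit, role = a$role)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
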