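# CSV dialects and JSON result serialisation.
#
# Spectrum CSV:   wavelength_nm,value         (kind/label supplied by caller)
# Titration CSV:  protein_nM,time_h,fluorescence   (long format)
# Melt CSV:       temp_C,A390,A376  or  temp_C,ratio
# Dilution CSV:   concentration_M,absorbance
# QY CSV:         absorbance,integrated_emission
# R/T CSV:        wavelength_nm,R,T

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  stop_if(length(missing) > 0,
          sprintf("%s: missing column(s) %s", path,
                  paste(missing, collapse = ", ")))
}

#' Read a spectrum CSV
#'
#' @param path CSV with header `wavelength_nm,value`.
#' @param kind,label forwarded to [make_spectrum()] (the file itself does
#'   not carry them).
#' @return a [make_spectrum()] object.
#' @export
read_spectrum_csv <- function(path, kind = "absorbance", label = "") {
  df <- read.csv(path)
  require_columns(df, c("wavelength_nm", "value"), path)
  make_spectrum(df$wavelength_nm, df$value, kind, label)
}

#' Write a spectrum CSV
#'
#' @param spectrum a [make_spectrum()] object.
#' @param path output path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  write.csv(as.data.frame(spectrum), path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format titration CSV
#'
#' @param path CSV with header `protein_nM,time_h,fluorescence`.
#' @param ligand_total_nM fixed limiting-ligand concentration, nM.
#' @param emission_wavelength nm tag.
#' @return a [titration_series()] (fluorescence matrix if multiple
#'   timepoints are present).
#' @export
read_titration_csv <- function(path, ligand_total_nM,
                               emission_wavelength = 697) {
  df <- read.csv(path)
  require_columns(df, c("protein_nM", "time_h", "fluorescence"), path)
  conc <- sort(unique(df$protein_nM))
  times <- sort(unique(df$time_h))
  f <- matrix(NA_real_, length(conc), length(times))
  for (r in seq_len(nrow(df))) {
    i <- match(df$protein_nM[r], conc)
    j <- match(df$time_h[r], times)
    f[i, j] <- df$fluorescence[r]
  }
  stop_if(any(is.na(f)), sprintf("%s: ragged concentration x time table",
                                 path))
  if (length(times) == 1L) {
    titration_series(conc * 1e-9, ligand_total_nM * 1e-9, f[, 1],
                     emission_wavelength = emission_wavelength)
  } else {
    titration_series(conc * 1e-9, ligand_total_nM * 1e-9, f,
                     timepoints = times,
                     emission_wavelength = emission_wavelength)
  }
}

#' Write a titration series as long-format CSV
#'
#' @param series a [titration_series()].
#' @param path output path.
#' @export
write_titration_csv <- function(series, path) {
  f <- series$fluorescence
  if (!is.matrix(f)) {
    df <- data.frame(protein_nM = series$protein_concentrations * 1e9,
                     time_h = 0, fluorescence = f)
  } else {
    df <- expand.grid(protein_nM = series$protein_concentrations * 1e9,
                      time_h = series$timepoints)
    df$fluorescence <- as.vector(f)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a melt CSV
#'
#' Accepts either `temp_C,A390,A376` (the ratio is computed) or
#' `temp_C,ratio`.
#'
#' @param path CSV path.
#' @return a [melt_curve()].
#' @export
read_melt_csv <- function(path) {
  df <- read.csv(path)
  stop_if(!("temp_C" %in% names(df)), sprintf("%s: missing column temp_C",
                                              path))
  if (all(c("A390", "A376") %in% names(df))) {
    melt_curve(df$temp_C, df$A390 / df$A376)
  } else {
    require_columns(df, "ratio", path)
    melt_curve(df$temp_C, df$ratio)
  }
}

#' Read a reflectance/transmittance CSV
#'
#' @param path CSV with header `wavelength_nm,R,T`.
#' @return list of [rt_measurement()] objects.
#' @export
read_rt_csv <- function(path) {
  df <- read.csv(path)
  require_columns(df, c("wavelength_nm", "R", "T"), path)
  lapply(seq_len(nrow(df)), function(i)
    rt_measurement(df$R[i], df$T[i], df$wavelength_nm[i]))
}

#' Write an analysis result as JSON
#'
#' Results are serialised field-for-field (class attributes dropped,
#' data.frame members as column lists). Wall-clock values are never
#' included, so identical runs produce identical files.
#'
#' @param result any result object (list-like).
#' @param path output path.
#' @export
write_result_json <- function(result, path) {
  clean <- rapply(unclass(result), function(x) x, how = "replace")
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
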