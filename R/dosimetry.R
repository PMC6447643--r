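# CT dose bookkeeping: SSDE, DLP, effective dose.

# 32-cm-phantom size conversion factor, exponential fit to the AAPM Report
# 204 table (valid 6-55 cm effective diameter; within 1% of the table).
f32 <- function(effective_diameter) {
  3.704369 * exp(-0.03671937 * effective_diameter)
}

#' Size-specific dose estimate
#'
#' Scales the 32-cm-phantom volume CT dose index by the patient-size
#' conversion factor `f(d) = 3.704369 * exp(-0.03671937 * d)`.
#'
#' @param ctdi_vol_32 CTDIvol referenced to the 32-cm phantom (mGy), >= 0.
#' @param effective_diameter patient effective diameter (cm), within the
#'   6-55 cm validity range of the conversion.
#' @return SSDE (mGy).
#' @export
ssde <- function(ctdi_vol_32, effective_diameter) {
  check_nonnegative(ctdi_vol_32, "ctdi_vol_32")
  if (!is.numeric(effective_diameter) || length(effective_diameter) != 1L ||
      effective_diameter < 6 || effective_diameter > 55)
    fpact_abort("effective_diameter outside the 6-55 cm conversion validity range",
                "fpact_range")
  ctdi_vol_32 * f32(effective_diameter)
}

#' Effective dose from CTDIvol and scan length
#'
#' `E = k * DLP` with `DLP = CTDIvol * L`.
#'
#' @param ctdi_vol dose index (mGy), >= 0 (use the SSDE for a size-specific
#'   effective dose).
#' @param scan_length craniocaudal coverage (cm), >= 0.
#' @param k_factor body-region conversion factor (mSv/(mGy*cm)), default
#'   0.014 (adult chest).
#' @return effective dose (mSv).
#' @export
effective_dose <- function(ctdi_vol, scan_length, k_factor = 0.014) {
  check_nonnegative(ctdi_vol, "ctdi_vol")
  check_nonnegative(scan_length, "scan_length")
  check_positive(k_factor, "k_factor")
  k_factor * ctdi_vol * scan_length
}

#' Protocol dose report
#'
#' Full dose chain for a two-volume protocol: SSDE, DLP, effective dose and
#' size-specific effective dose, with values rounded to one decimal for
#' report parity alongside the raw numbers.
#'
#' @param ctdi_vol_32 CTDIvol (32-cm phantom, mGy).
#' @param effective_diameter effective diameter (cm).
#' @param scan_length craniocaudal coverage (cm).
#' @param k_factor conversion factor (mSv/(mGy*cm)).
#' @return a list of class `dose_report`.
#' @export
dose_report <- function(ctdi_vol_32, effective_diameter, scan_length,
                        k_factor = 0.014) {
  s <- ssde(ctdi_vol_32, effective_diameter)
  e <- effective_dose(ctdi_vol_32, scan_length, k_factor)
  es <- effective_dose(s, scan_length, k_factor)
  structure(
    list(ctdi_vol_32 = ctdi_vol_32, ssde = s,
         dlp = ctdi_vol_32 * scan_length,
         effective_dose = e, size_specific_effective_dose = es,
         rounded = list(ssde = round(s, 1), effective_dose = round(e, 1),
                        size_specific_effective_dose = round(es, 1))),
    class = "dose_report"
  )
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf("CTDIvol(32) %.1f mGy -> SSDE %.1f mGy; E %.1f mSv, size-specific E %.1f mSv\n",
              x$ctdi_vol_32, x$rounded$ssde, x$rounded$effective_dose,
              x$rounded$size_specific_effective_dose))
  invisible(x)
}
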