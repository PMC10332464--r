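## The catecholamine normalization chain.  Symbols follow HPLC-ECD
## bookkeeping practice: C_Std standard concentration (ng/mL), A_Std /
## A_Samp peak areas of the standard and sample runs, I_Std / I_Samp
## injection volumes (uL), N fly heads pooled, P_Samp protein concentration
## of the extract (ug/uL).  The chain:
##   V1 = C_Std * I_Std / 1000            ng on column from the standard
##   V2 = A_Samp * V1 / A_Std             ng on column in the sample run
##   V3 = P_Samp * I_Samp                 ug protein injected
##   V4 = V2 / V3                         ng per ug protein
##   V5 = V2 * extract_volume / I_Samp    ng in the whole extract
##   V6 = V5 / N                          ng per fly head
##   V7 = V6 / dilution_factor            corrected for the 1:1 TCA mix
##   V8 = V7 * 1000                       pg per fly head
## V5 (total analyte in the extract) is the only reading under which
## V6 = V5 / N is dimensionally "per fly head"; extract_volume defaults to
## the protocol's 300 uL homogenate and is echoed in the output.

#' Complete the catecholamine quantification chain
#'
#' @param C_Std Standard concentration, ng/mL (> 0).
#' @param A_Std Peak area of the analyte in the standard run (> 0).
#' @param I_Std Standard injection volume, uL (> 0).
#' @param A_Samp Peak area of the analyte in the sample run (> 0).
#' @param I_Samp Sample injection volume, uL (> 0).
#' @param N Number of fly heads pooled (integer >= 1).
#' @param P_Samp Total protein concentration of the extract, ug/uL (> 0).
#' @param extract_volume Whole-extract volume, uL (default 300).
#' @param dilution_factor Dilution from mixing with TCA (default 2 for the
#'   1:1 mix).
#' @param analyte Optional label.
#' @return An object of class `catecholamine_quant`: all inputs plus
#'   `V1`..`V8` and a `note` documenting the V5 interpretation.
#' @export
quantify_catecholamine <- function(C_Std, A_Std, I_Std, A_Samp, I_Samp, N,
                                   P_Samp, extract_volume = 300,
                                   dilution_factor = 2, analyte = NULL) {
  for (nm in c("C_Std", "A_Std", "I_Std", "A_Samp", "I_Samp", "N",
               "P_Samp", "extract_volume", "dilution_factor")) {
    assert_number(get(nm), nm, positive = TRUE)
  }
  assert_number(N, "N", positive = TRUE, integer = TRUE)
  V1 <- C_Std * I_Std / 1000
  V2 <- A_Samp * V1 / A_Std
  V3 <- P_Samp * I_Samp
  V4 <- V2 / V3
  V5 <- V2 * extract_volume / I_Samp
  V6 <- V5 / N
  V7 <- V6 / dilution_factor
  V8 <- V7 * 1000
  structure(
    list(analyte = analyte, C_Std = C_Std, A_Std = A_Std, I_Std = I_Std,
         A_Samp = A_Samp, I_Samp = I_Samp, N = N, P_Samp = P_Samp,
         extract_volume = extract_volume, dilution_factor = dilution_factor,
         V1 = V1, V2 = V2, V3 = V3, V4 = V4, V5 = V5, V6 = V6, V7 = V7,
         V8 = V8,
         note = paste("V5 interpreted as total analyte in the whole",
                      "extract: V2 * extract_volume / I_Samp")),
    class = "catecholamine_quant")
}

#' @export
print.catecholamine_quant <- function(x, ...) {
  cat(sprintf("<catecholamine_quant>%s\n",
              if (!is.null(x$analyte)) paste0(" ", x$analyte) else ""))
  v <- unlist(x[paste0("V", 1:8)])
  units <- c("ng", "ng", "ug", "ng/ug", "ng", "ng", "ng", "pg")
  for (i in 1:8) cat(sprintf("  V%d = %.6g %s\n", i, v[i], units[i]))
  invisible(x)
}

#' @export
as.data.frame.catecholamine_quant <- function(x, ...) {
  x$note <- NULL
  as.data.frame(unclass(x)[!vapply(unclass(x), is.null, TRUE)], ...)
}

#' Dopamine oxidative turnover ratio
#'
#' `(DOPAC + HVA) / DA`: the standard index of dopamine turnover, elevated
#' when DA is metabolized faster than it is replenished.  All three inputs
#' must share units.
#'
#' @param da Dopamine level (> 0).
#' @param dopac,hva Metabolite levels (>= 0).
#' @return Dimensionless ratio.
#' @export
turnover_ratio <- function(da, dopac, hva) {
  assert_number(dopac, "dopac", nonneg = TRUE)
  assert_number(hva, "hva", nonneg = TRUE)
  if (!is.numeric(da) || length(da) != 1L || is.na(da) || da <= 0) {
    stop("turnover undefined: 'da' must be > 0")
  }
  (dopac + hva) / da
}
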