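#' Default examination-item registry
#'
#' The 42 routine medical-examination items (EIs) used throughout the
#' pipeline, grouped into the five clinical categories recorded at
#' discharge: basic information (3 items), biochemical test (18), blood
#' test (5), echocardiography (9), and urine test (7).
#'
#' Item names follow common clinical abbreviations: `LVDS`/`LVEDD` are the
#' left ventricular end systolic/diastolic diameters (mm), `ALT` alanine
#' aminotransferase (U/L), `U_EC` the urine epithelial cell count,
#' `U_ECH` urine epithelial cells per high-power field, `UA` uric acid,
#' `CKMB_CK` the creatine kinase isozyme / creatine kinase ratio and
#' `GGT` gamma-glutamyl transpeptidase.
#'
#' @return A tibble with columns `item`, `category`, and `unit`.
#' @export
#' @examples
#' dplyr::count(default_item_registry(), category)
default_item_registry <- function() {
  reg <- list(
    basic = c(age = "years", height = "cm", weight = "kg"),
    biochemical = c(
      ALT = "U/L", AST = "U/L", GGT = "U/L", ALP = "U/L", LDH = "U/L",
      UA = "umol/L", CKMB_CK = "ratio", TBIL = "umol/L", DBIL = "umol/L",
      ALB = "g/L", TP = "g/L", BUN = "mmol/L", CREA = "umol/L",
      GLU = "mmol/L", TC = "mmol/L", TG = "mmol/L", HDL = "mmol/L",
      LDL = "mmol/L"
    ),
    blood = c(WBC = "10^9/L", RBC = "10^12/L", HGB = "g/L",
              PLT = "10^9/L", NEUT = "%"),
    echocardiography = c(
      LVDS = "mm", LVEDD = "mm", EF = "%", FS = "%", AO = "mm", LA = "mm",
      IVS = "mm", LVPW = "mm", E_A = "ratio"
    ),
    urine = c(U_EC = "count", U_ECH = "count/HPF", U_WBC = "count",
              U_RBC = "count", U_SG = "ratio", U_PH = "pH", U_CAST = "count")
  )
  tibble::tibble(
    item = unlist(lapply(reg, names), use.names = FALSE),
    category = rep(names(reg), lengths(reg)),
    unit = unlist(reg, use.names = FALSE)
  )
}

# Non-EI columns every cohort table must carry, in canonical order.
cohort_core_columns <- function() c("id", "mir194", "bmd", "t_score")
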