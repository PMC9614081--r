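`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_pedcvh <- function(fmt, ..., class = "pedcvh_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "pedcvh_error")))
}

#' Metric status factor
#'
#' Builds the ordered poor < intermediate < ideal factor used for every CVH
#' metric classification.
#'
#' @param x character vector of statuses (may contain NA).
#' @return ordered factor with levels poor, intermediate, ideal.
#' @export
status_factor <- function(x) {
  factor(x, levels = c("poor", "intermediate", "ideal"), ordered = TRUE)
}

SEX_LEVELS <- c("male", "female")

check_sex <- function(sex) {
  if (!all(sex %in% SEX_LEVELS)) {
    stop_pedcvh("sex must be one of %s", paste(SEX_LEVELS, collapse = "/"))
  }
  sex
}

#' Unit conversion to the package's canonical mg/dL
#'
#' Total cholesterol is stored internally in mg/dL (1 mmol/L = 38.67 mg/dL);
#' glucose likewise (1 mmol/L = 18.016 mg/dL).
#'
#' @param x numeric concentrations.
#' @param analyte "tc" or "glucose".
#' @param from "mg/dL" or "mmol/L".
#' @return numeric vector in mg/dL.
#' @export
to_mgdl <- function(x, analyte = c("tc", "glucose"), from = c("mg/dL", "mmol/L")) {
  analyte <- match.arg(analyte)
  from <- match.arg(from)
  if (from == "mg/dL") return(x)
  x * switch(analyte, tc = 38.67, glucose = 18.016)
}
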