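#' Dichotomize an ABSOLUTE-style ploidy estimate
#'
#' A continuous tumor ploidy value is called diploid when it lies within
#' 2 +/- 0.05 (boundary inclusive); values outside the interval are
#' aneuploid.
#'
#' @param value Positive numeric ploidy estimate(s).
#' @return Character vector of `"diploid"` / `"aneuploid"` calls.
#' @export
absolute_ploidy_call <- function(value) {
  if (any(value <= 0)) stop("ploidy value must be positive")
  # small tolerance so the inclusive boundary survives binary rounding of 0.05
  ifelse(abs(value - 2) <= 0.05 + 1e-9, "diploid", "aneuploid")
}

#' Immunohistochemistry staining index
#'
#' Staining index (SI) = area grade (0-3) x intensity grade (0-3), so
#' SI takes values in \{0,1,2,3,4,6,9\}. Marker-specific quartile
#' dichotomization: STAG2 (nuclear) low expression at SI 0-1;
#' PPP2R3A (cytoplasmic) high expression at SI 6-9. Values outside the
#' marker's dichotomizing quartile are `"intermediate"`.
#'
#' @param area,intensity Integer grades in 0-3.
#' @param marker `"STAG2"` or `"PPP2R3A"`.
#' @return A `staining_record`: list `area_grade`, `intensity_grade`,
#'   `si`, `marker`, `call` (`"low"`, `"high"` or `"intermediate"`).
#' @export
staining_index <- function(area, intensity, marker = c("STAG2", "PPP2R3A")) {
  marker <- match.arg(marker)
  ok <- function(g) length(g) == 1 && is.finite(g) && g == round(g) && g >= 0 && g <= 3
  if (!ok(area) || !ok(intensity))
    stop("area and intensity grades must be integers in 0-3")
  si <- as.integer(area) * as.integer(intensity)
  call <- if (marker == "STAG2") {
    if (si <= 1) "low" else "intermediate"
  } else {
    if (si >= 6) "high" else "intermediate"
  }
  structure(list(area_grade = as.integer(area), intensity_grade = as.integer(intensity),
                 si = si, marker = marker, call = call),
            class = "staining_record")
}

#' Collapse raw flow-cytometry ploidy labels to a binary call
#'
#' Tetraploid and triploid tumors are grouped with the aneuploid class
#' (their numbers are typically too low for separate analysis); diploid
#' and aneuploid labels pass through unchanged.
#'
#' @param raw Character vector over \{diploid, aneuploid, tetraploid,
#'   triploid\}.
#' @return Character vector of `"diploid"` / `"aneuploid"`.
#' @export
flow_label_collapse <- function(raw) {
  known <- c(diploid = "diploid", aneuploid = "aneuploid",
             tetraploid = "aneuploid", triploid = "aneuploid")
  bad <- setdiff(unique(raw), names(known))
  if (length(bad)) stop("unknown ploidy label(s): ", paste(bad, collapse = ", "))
  unname(known[raw])
}
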