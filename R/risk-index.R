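#' Contamination factor
#'
#' The contamination factor \eqn{C_r} of a metal is its measured
#' concentration divided by the regulatory reference concentration.
#' Both arguments are in mg/kg; the result is dimensionless. Vectorized.
#'
#' @param conc measured concentration(s), nonnegative.
#' @param ref reference concentration(s), strictly positive.
#' @return \code{conc / ref}.
#' @examples
#' contaminationFactor(0.30, 0.15)  # 2
#' @export
contaminationFactor <- function(conc, ref) {
  if (any(!is.finite(ref)) || any(ref <= 0))
    stop("invalid reference: reference concentrations must be > 0")
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("invalid concentration: concentrations must be >= 0 and finite")
  conc / ref
}

#' Per-metal ecological risk factor
#'
#' The ecological risk factor of metal \eqn{i} is
#' \eqn{E_r^i = T_r^i \times C_r^i}: the toxic-response factor times the
#' contamination factor.
#'
#' @param panel a [MetalPanel-class].
#' @param metal metal symbol, must be in the panel.
#' @param cf contamination factor(s).
#' @return \eqn{E_r} value(s).
#' @examples
#' ref <- c(Cr = 250, Ni = 60, Zn = 300, Hg = 1, Cu = 100, As = 30,
#'          Cd = 0.6, Pb = 350)
#' ecologicalRisk(MetalPanel(ref), "Hg", 1)  # 40
#' @export
ecologicalRisk <- function(panel, metal, cf) {
  stopifnot(is(panel, "MetalPanel"))
  if (!metal %in% metals(panel))
    stop(sprintf("unknown metal '%s': not in panel", metal))
  unname(toxicResponse(panel)[metal]) * cf
}

.GRADE_LEVELS <- c("low", "moderate", "considerable", "high", "very_high")
.GRADE_BREAKS <- c(40, 80, 160, 320)

#' Grade a per-metal ecological risk value
#'
#' Risk grades follow the conventional thresholds:
#' \eqn{E_r < 40} low; \eqn{[40, 80)} moderate; \eqn{[80, 160)}
#' considerable; \eqn{[160, 320)} high; \eqn{\ge 320} very high. The
#' boundary value 320, which the strict published inequalities leave
#' unassigned, is graded \code{very_high}. Vectorized.
#'
#' @param er nonnegative \eqn{E_r} value(s).
#' @return factor with levels low < moderate < considerable < high <
#'   very_high.
#' @export
gradeRisk <- function(er) {
  if (any(!is.finite(er)) || any(er < 0))
    stop("invalid risk value: E_r must be >= 0 and finite")
  idx <- findInterval(er, .GRADE_BREAKS) + 1L
  factor(.GRADE_LEVELS[idx], levels = .GRADE_LEVELS, ordered = TRUE)
}

#' Total potential ecological risk index
#'
#' The Hakanson potential ecological risk index RI aggregates the
#' per-metal risk factors by summation over the full eight-metal panel:
#' \eqn{RI = \sum_i E_r^i}. With all contamination factors equal to 1 and
#' default toxic-response factors, RI equals 103 (the sum of the factors).
#'
#' @param er named numeric vector of \eqn{E_r} values covering all eight
#'   panel metals, or a matrix with one column per metal.
#' @return scalar RI (or vector, for matrix input).
#' @export
totalRI <- function(er) {
  if (is.matrix(er) || is.data.frame(er)) {
    er <- as.matrix(er)
    miss <- setdiff(.PANEL_METALS, colnames(er))
    if (length(miss))
      stop(sprintf("incomplete panel: missing metal(s) %s",
                   paste(miss, collapse = ", ")))
    return(rowSums(er[, .PANEL_METALS, drop = FALSE]))
  }
  miss <- setdiff(.PANEL_METALS, names(er))
  if (length(miss))
    stop(sprintf("incomplete panel: missing metal(s) %s",
                 paste(miss, collapse = ", ")))
  sum(er[.PANEL_METALS])
}

#' Score point samples against a metal panel
#'
#' Computes, for each sample, the contamination factor, ecological risk
#' factor and risk grade of every panel metal plus the total RI.
#'
#' @param samples data.frame with a \code{sample_id} column and one
#'   concentration column (mg/kg) per panel metal. Extra columns (e.g.
#'   lon/lat) are carried through untouched in the ordering but not
#'   returned.
#' @param panel a [MetalPanel-class].
#' @return data.frame with columns \code{subject_id}, \code{cf_<metal>},
#'   \code{er_<metal>}, \code{ri} and \code{grade_<metal>}, rows in input
#'   order.
#' @export
scoreSamples <- function(samples, panel) {
  stopifnot(is(panel, "MetalPanel"))
  samples <- as.data.frame(samples)
  if (nrow(samples) < 1L) stop("at least one sample is required")
  if (!"sample_id" %in% names(samples))
    stop("samples must have a 'sample_id' column")
  miss <- setdiff(metals(panel), names(samples))
  if (length(miss))
    stop(sprintf("schema error: sample table lacks metal column(s) %s",
                 paste(miss, collapse = ", ")))
  conc <- as.matrix(samples[, metals(panel), drop = FALSE])
  bad <- which(!is.finite(conc) | conc < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid concentration for sample '%s', metal %s",
                 samples$sample_id[bad[1L, 1L]],
                 metals(panel)[bad[1L, 2L]]))
  ref <- referenceValues(panel)[metals(panel)]
  tr <- toxicResponse(panel)[metals(panel)]
  cf <- sweep(conc, 2L, ref, "/")
  er <- sweep(cf, 2L, tr, "*")
  out <- data.frame(subject_id = samples$sample_id,
                    stringsAsFactors = FALSE)
  for (m in metals(panel)) out[[paste0("cf_", m)]] <- cf[, m]
  for (m in metals(panel)) out[[paste0("er_", m)]] <- er[, m]
  out$ri <- rowSums(er)
  for (m in metals(panel))
    out[[paste0("grade_", m)]] <- as.character(gradeRisk(er[, m]))
  out
}

#' Read a point-sample table
#'
#' Expects a UTF-8 CSV with header
#' \code{sample_id,lon,lat,Cr,Ni,Zn,Hg,Cu,As,Cd,Pb} (concentrations in
#' mg/kg).
#'
#' @param path CSV path.
#' @return data.frame of samples.
#' @export
readSamples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "lon", "lat", .PANEL_METALS)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("sample CSV lacks column(s): %s",
                 paste(miss, collapse = ", ")))
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Write risk scores to CSV
#'
#' @param scores output of [scoreSamples()].
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
writeRiskResults <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
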