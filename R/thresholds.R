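#' Differential-expression thresholds
#'
#' Bundle of cutoffs applied when calling a feature differentially expressed.
#' Fold-change cutoffs are expressed on the linear scale and compared against
#' `2^|log2fc|`; both comparisons are strict, so a feature sitting exactly at
#' the fold-change or p-value boundary is *not* called DE.
#'
#' The defaults (`|FC| > 1.2`, `p < 0.05` on the nominal p-value) are the
#' conventional gene-level integration thresholds in the pulmonary fibrosis
#' meta-analysis literature. miRNA integration conventionally uses the
#' FDR-adjusted p-value instead: set `use_adjusted = TRUE`.
#'
#' @param min_abs_fc Linear absolute fold-change cutoff, must be > 1.
#' @param max_p P-value cutoff in (0, 1).
#' @param use_adjusted If `TRUE`, the FDR-adjusted p-value is thresholded
#'   instead of the nominal one.
#' @return An object of class `de_thresholds` (a named list).
#' @examples
#' de_thresholds()                      # gene defaults
#' de_thresholds(use_adjusted = TRUE)   # miRNA defaults
#' @export
de_thresholds <- function(min_abs_fc = 1.2, max_p = 0.05, use_adjusted = FALSE) {
  stopifnot(is.numeric(min_abs_fc), length(min_abs_fc) == 1L, is.finite(min_abs_fc))
  stopifnot(is.numeric(max_p), length(max_p) == 1L, is.finite(max_p))
  if (min_abs_fc <= 1) abort("`min_abs_fc` must be > 1 (linear fold change).")
  if (max_p <= 0 || max_p >= 1) abort("`max_p` must lie strictly within (0, 1).")
  structure(
    list(min_abs_fc = min_abs_fc, max_p = max_p,
         use_adjusted = isTRUE(use_adjusted)),
    class = "de_thresholds"
  )
}

#' @export
print.de_thresholds <- function(x, ...) {
  cat(sprintf("DE thresholds: |FC| > %g, %s p < %g\n",
              x$min_abs_fc, if (x$use_adjusted) "adjusted" else "nominal",
              x$max_p))
  invisible(x)
}

as_de_thresholds <- function(x) {
  if (inherits(x, "de_thresholds")) return(x)
  if (is.list(x)) return(do.call(de_thresholds, x))
  abort("Expected a `de_thresholds` object (see `de_thresholds()`).")
}

#' Classify features as up-, down-, or not differentially expressed
#'
#' Vectorised DE call: a feature is `up` when `2^log2fc` strictly exceeds the
#' linear fold-change cutoff and its p-value is strictly below the cutoff;
#' `down` symmetrically for `2^(-log2fc)`; otherwise `non_de`. Missing
#' statistics never produce a DE call — such features are classified `non_de`
#' and a warning summarises how many were affected.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param p Numeric vector of p-values (nominal or adjusted — the caller picks
#'   the column matching `thresholds$use_adjusted`).
#' @param thresholds A [de_thresholds()] object.
#' @return Factor with levels `up`, `down`, `non_de`.
#' @examples
#' classify_de(c(1, -2, 0.1), c(0.01, 0.049, 0.2), de_thresholds())
#' @export
classify_de <- function(log2fc, p, thresholds = de_thresholds()) {
  thresholds <- as_de_thresholds(thresholds)
  if (length(log2fc) != length(p)) {
    abort("`log2fc` and `p` must have equal length.")
  }
  miss <- !is.finite(log2fc) | !is.finite(p)
  if (any(miss)) {
    warn(sprintf("%d feature(s) with missing statistics classified as non_de.",
                 sum(miss)))
  }
  up <- !miss & 2^log2fc > thresholds$min_abs_fc & p < thresholds$max_p
  dn <- !miss & 2^(-log2fc) > thresholds$min_abs_fc & p < thresholds$max_p
  factor(ifelse(up, "up", ifelse(dn, "down", "non_de")),
         levels = c("up", "down", "non_de"))
}

# Per-table DE calls using the p-value column selected by the thresholds.
de_calls <- function(table, thresholds) {
  thresholds <- as_de_thresholds(thresholds)
  p <- if (thresholds$use_adjusted) table$p_adjusted else table$p_nominal
  classify_de(table$log2fc, p, thresholds)
}
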