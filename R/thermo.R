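#' Duplex parameters for the Wetmur DNA:DNA melting model
#'
#' Bundles the duplex-side symbols of the Wetmur melting-temperature model:
#' GC content, duplex length and percent mismatch between probe and target.
#'
#' @param gc_percent Percent GC content of the probe (0-100).
#' @param length_bp Duplex length N in base pairs (integer >= 1).
#' @param mismatch_percent Percent mismatch M between probe and target
#'   (0-100). Mismatch percent is defined as `100 - percent identity` of the
#'   probe-target alignment, tying this module to [align_probe()].
#'
#' @return An object of class `duplex_params`.
#' @seealso [hyb_conditions()], [wetmur_tm()]
#' @export
#' @examples
#' duplex_params(gc_percent = 50, length_bp = 450)
duplex_params <- function(gc_percent, length_bp, mismatch_percent = 0) {
  stopifnot(is.numeric(gc_percent), is.numeric(length_bp), is.numeric(mismatch_percent))
  if (any(gc_percent < 0 | gc_percent > 100))
    stop("gc_percent must be in [0, 100]", call. = FALSE)
  if (any(length_bp < 1))
    stop("length_bp must be >= 1", call. = FALSE)
  if (any(mismatch_percent < 0 | mismatch_percent > 100))
    stop("mismatch_percent must be in [0, 100]", call. = FALSE)
  structure(list(gc_percent = gc_percent, length_bp = length_bp,
                 mismatch_percent = mismatch_percent),
            class = "duplex_params")
}

#' Hybridization conditions
#'
#' Solution-side parameters of a hybridization: monovalent sodium
#' concentration, formamide concentration, hybridization temperature and an
#' optional safety margin by which the duplex Tm must exceed the
#' hybridization temperature for a target to count as detectable.
#'
#' The defaults (`na_molar = 0.39`, `hyb_temp_c = 46`) are
#' protocol-dependent placeholders typical of geneFISH hybridization
#' buffers; set them to your protocol's values.
#'
#' @param na_molar Molar Na+ concentration (> 0).
#' @param fa_percent Formamide concentration, % v/v (0-100).
#' @param hyb_temp_c Hybridization temperature, degrees Celsius.
#' @param tm_margin_c Required excess of Tm over `hyb_temp_c` (default 0).
#'
#' @return An object of class `hyb_conditions`.
#' @export
#' @examples
#' hyb_conditions(fa_percent = 35)
hyb_conditions <- function(na_molar = 0.39, fa_percent = 0, hyb_temp_c = 46,
                           tm_margin_c = 0) {
  stopifnot(is.numeric(na_molar), is.numeric(fa_percent), is.numeric(hyb_temp_c))
  if (any(na_molar <= 0))
    stop("na_molar must be > 0", call. = FALSE)
  if (any(fa_percent < 0 | fa_percent > 100))
    stop("fa_percent must be in [0, 100]", call. = FALSE)
  structure(list(na_molar = na_molar, fa_percent = fa_percent,
                 hyb_temp_c = hyb_temp_c, tm_margin_c = tm_margin_c),
            class = "hyb_conditions")
}

#' Wetmur melting temperature for DNA:DNA duplexes
#'
#' Empirical closed-form melting temperature of a DNA:DNA duplex:
#'
#' \deqn{Tm = 81.5 + 16.6 \log_{10}\left(\frac{[Na^+]}{1 + 0.7 [Na^+]}\right)
#'       + 0.41\, GC - \frac{500}{N} - M - 0.63\, FA}
#'
#' with GC in percent, N the duplex length in bp, M the percent mismatch and
#' FA the percent formamide. The value is returned unclamped (it may exceed
#' 100 or fall below 0 degrees C); detectability decisions compare it to the
#' hybridization temperature plus margin, see [max_mismatch()].
#'
#' @param duplex A [duplex_params()] object (fields may be vectors).
#' @param cond A [hyb_conditions()] object.
#'
#' @return Melting temperature(s) in degrees Celsius.
#' @export
#' @examples
#' wetmur_tm(duplex_params(50, 450), hyb_conditions(na_molar = 0.39, fa_percent = 35))
wetmur_tm <- function(duplex, cond) {
  stopifnot(inherits(duplex, "duplex_params"), inherits(cond, "hyb_conditions"))
  na <- cond$na_molar
  81.5 + 16.6 * log10(na / (1 + 0.7 * na)) + 0.41 * duplex$gc_percent -
    500 / duplex$length_bp - duplex$mismatch_percent - 0.63 * cond$fa_percent
}

#' Maximum tolerated mismatch at given hybridization conditions
#'
#' The mismatch percentage that brings the duplex Tm down to the
#' hybridization temperature plus safety margin. Because mismatch enters the
#' Wetmur model with coefficient -1, this is simply
#' `Tm(M = 0) - (hyb_temp_c + tm_margin_c)`, floored at 0. A target is
#' predicted detectable iff its mismatch to the probe is at most this value.
#'
#' @inheritParams wetmur_tm
#' @return Maximum mismatch percent (>= 0). If the perfectly matched duplex
#'   is already unstable (`Tm(M=0)` below the hybridization temperature plus
#'   margin) the result is 0 with attribute `unstable = TRUE` and a warning.
#' @export
#' @examples
#' max_mismatch(duplex_params(50, 450), hyb_conditions(fa_percent = 15))
max_mismatch <- function(duplex, cond) {
  d0 <- duplex
  d0$mismatch_percent <- 0
  m <- wetmur_tm(d0, cond) - (cond$hyb_temp_c + cond$tm_margin_c)
  unstable <- m < 0
  if (any(unstable)) {
    warning("probe unstable even with perfect match at these conditions",
            call. = FALSE)
    m[unstable] <- 0
  }
  attr(m, "unstable") <- unstable
  m
}

#' Recommend a relaxed formamide concentration
#'
#' Given a stringent design formamide concentration and the mismatch load of
#' a cross-taxon target one wishes to also detect, returns the formamide
#' concentration whose Tm gain exactly compensates the mismatch Tm penalty
#' under the Wetmur coefficients: `FA_relaxed = stringent_fa - M / 0.63`.
#' By default the result is rounded to the nearest multiple of 5, matching
#' how hybridization buffers are prepared in 5% formamide steps.
#'
#' @param stringent_fa Stringent design-point formamide concentration, percent.
#' @param target_mismatch Mismatch percent of the most divergent target to
#'   be captured (`100 - percent identity`).
#' @param rounding `"nearest-5"` (default), `"nearest-5-down"`, or `"none"`.
#'
#' @return Recommended formamide percent, floored at 0. If the unrounded
#'   value is negative, the mismatch cannot be fully compensated by lowering
#'   formamide alone and a warning is emitted.
#' @export
#' @examples
#' recommend_fa(35, 14)          # 86% identity target -> 15% formamide
#' recommend_fa(35, 6.3, "none") # 25
recommend_fa <- function(stringent_fa, target_mismatch,
                         rounding = c("nearest-5", "nearest-5-down", "none")) {
  rounding <- match.arg(rounding)
  stopifnot(stringent_fa >= 0, stringent_fa <= 100,
            target_mismatch >= 0, target_mismatch <= 100)
  fa <- stringent_fa - target_mismatch / 0.63
  if (any(fa < 0))
    warning("mismatch cannot be fully compensated by formamide alone; ",
            "recommendation floored at 0% FA", call. = FALSE)
  fa <- switch(rounding,
               "none" = fa,
               "nearest-5" = 5 * round(fa / 5),
               "nearest-5-down" = 5 * floor(fa / 5))
  pmax(fa, 0)
}

#' Melting-temperature grid over formamide and mismatch
#'
#' Evaluates the Wetmur Tm over the cross-product of formamide and mismatch
#' values and derives the two stringency curves used when choosing
#' hybridization conditions: the maximum tolerated mismatch as a function of
#' formamide, and the formamide required to tolerate a given mismatch.
#'
#' @inheritParams wetmur_tm
#' @param fa_values Formamide grid, percent (non-empty).
#' @param mismatch_values Mismatch grid, percent (non-empty).
#'
#' @return An object of class `stringency_envelope`: a list with
#'   `grid` (data.frame fa_percent, mismatch_percent, tm_c),
#'   `max_mismatch` (data.frame fa_percent, max_mismatch_percent) and
#'   `required_fa` (data.frame mismatch_percent, required_fa_percent, where
#'   values above 100 or below 0 are reported unclamped), plus the
#'   conditions used.
#' @export
#' @examples
#' env <- stringency_envelope(duplex_params(50, 450), hyb_conditions(),
#'                            fa_values = seq(0, 50, 5),
#'                            mismatch_values = seq(0, 30, 5))
#' head(env$grid)
stringency_envelope <- function(duplex, cond, fa_values, mismatch_values) {
  stopifnot(length(fa_values) >= 1, length(mismatch_values) >= 1)
  grid <- expand.grid(fa_percent = fa_values, mismatch_percent = mismatch_values,
                      KEEP.OUT.ATTRS = FALSE)
  dx <- duplex_params(duplex$gc_percent, duplex$length_bp, grid$mismatch_percent)
  cx <- hyb_conditions(cond$na_molar, grid$fa_percent, cond$hyb_temp_c, cond$tm_margin_c)
  grid$tm_c <- wetmur_tm(dx, cx)
  grid <- grid[order(grid$fa_percent, grid$mismatch_percent), , drop = FALSE]
  rownames(grid) <- NULL

  d0 <- duplex_params(duplex$gc_percent, duplex$length_bp, 0)
  c0 <- hyb_conditions(cond$na_molar, 0, cond$hyb_temp_c, cond$tm_margin_c)
  tm00 <- wetmur_tm(d0, c0)  # Tm at M = 0, FA = 0
  thr <- cond$hyb_temp_c + cond$tm_margin_c
  fa_sorted <- sort(unique(fa_values))
  mm_sorted <- sort(unique(mismatch_values))
  mm_curve <- data.frame(fa_percent = fa_sorted,
                         max_mismatch_percent = pmax(tm00 - 0.63 * fa_sorted - thr, 0))
  fa_curve <- data.frame(mismatch_percent = mm_sorted,
                         required_fa_percent = (tm00 - mm_sorted - thr) / 0.63)
  structure(list(grid = grid, max_mismatch = mm_curve, required_fa = fa_curve,
                 duplex = duplex, cond = cond),
            class = "stringency_envelope")
}

#' @export
print.stringency_envelope <- function(x, ...) {
  cat(sprintf("stringency envelope: %d FA x %d mismatch grid (GC %.1f%%, N %d bp, Na+ %.3g M)\n",
              length(unique(x$grid$fa_percent)), length(unique(x$grid$mismatch_percent)),
              x$duplex$gc_percent, as.integer(x$duplex$length_bp), x$cond$na_molar))
  print(head(x$grid, 10))
  invisible(x)
}

#' Write a stringency envelope to TSV files
#'
#' @param env A [stringency_envelope()] object.
#' @param grid_path Output path for the Tm grid TSV (columns `fa_percent`,
#'   `mismatch_percent`, `tm_c`).
#' @param curve_path Optional output path for the derived max-mismatch curve
#'   TSV (columns `fa_percent`, `max_mismatch_percent`).
#' @return Invisibly, the paths written.
#' @export
write_envelope_tsv <- function(env, grid_path, curve_path = NULL) {
  stopifnot(inherits(env, "stringency_envelope"))
  write_tsv_strict(env$grid, grid_path)
  if (!is.null(curve_path)) write_tsv_strict(env$max_mismatch, curve_path)
  invisible(c(grid_path, curve_path))
}
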