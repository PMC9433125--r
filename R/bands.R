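#' Canonical EEG rhythm definitions
#'
#' Returns the five classical scalp-EEG frequency bands used throughout the
#' package: delta 1--4, theta 4--8, alpha 8--12, beta 12--30 and gamma
#' 30--70 Hz. Band edges are half-open `[f_low, f_high)` so that shared
#' edges (4, 8, 12, 30 Hz) are counted in exactly one band.
#'
#' @param bands Optional character vector selecting a subset, in the order
#'   given. Default: all five.
#' @return A tibble with columns `band` (factor, ordered delta..gamma),
#'   `f_low` and `f_high` in Hz.
#' @examples
#' eeg_bands()
#' eeg_bands(c("delta", "theta"))
#' @export
eeg_bands <- function(bands = NULL) {
  tbl <- tibble::tibble(
    band   = factor(c("delta", "theta", "alpha", "beta", "gamma"),
                    levels = c("delta", "theta", "alpha", "beta", "gamma")),
    f_low  = c(1, 4, 8, 12, 30),
    f_high = c(4, 8, 12, 30, 70)
  )
  if (is.null(bands)) return(tbl)
  bad <- setdiff(bands, as.character(tbl$band))
  if (length(bad) > 0) {
    stop("unknown band(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tbl[match(bands, as.character(tbl$band)), , drop = FALSE]
}

#' @keywords internal
#' @noRd
band_definition <- function(name, f_low, f_high) {
  stopifnot(is.numeric(f_low), is.numeric(f_high))
  if (!(f_low > 0 && f_low < f_high)) {
    stop("band must satisfy 0 < f_low < f_high", call. = FALSE)
  }
  list(name = name, f_low = f_low, f_high = f_high)
}

# Resolve a band argument: a band name, a BandDefinition-like list, or
# "broadband" (NULL range -> no extra filtering beyond preprocessing).
resolve_band <- function(band) {
  if (is.character(band) && length(band) == 1) {
    if (identical(band, "broadband")) {
      return(list(name = "broadband", f_low = NA_real_, f_high = NA_real_))
    }
    b <- eeg_bands(band)
    return(band_definition(band, b$f_low, b$f_high))
  }
  if (is.list(band) && all(c("name", "f_low", "f_high") %in% names(band))) {
    if (identical(band$name, "broadband")) return(band)
    return(band_definition(band$name, band$f_low, band$f_high))
  }
  stop("band must be a band name, \"broadband\", or a list(name, f_low, f_high)",
       call. = FALSE)
}

state_levels <- function() c("inter_ictal", "pre_ictal", "ictal", "post_ictal")
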