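# Centralized unit conversions.
#
# User-facing interfaces work in MHz (linear frequency) and ns, the natural
# working units at X-band; all internal state is SI (Hz, s) or angular
# frequency (rad/s).

#' Unit conversion helpers
#'
#' Convert between the interface units (MHz, ns) and the internal units
#' (Hz, s, rad/s). `mhz_to_radsec()` multiplies by `2*pi*1e6`;
#' `radsec_to_mhz()` is its inverse.
#'
#' @param x numeric vector.
#' @return numeric vector in the target unit.
#' @keywords internal
#' @name units
NULL

#' @rdname units
#' @export
mhz_to_radsec <- function(x) 2 * pi * 1e6 * x

#' @rdname units
#' @export
radsec_to_mhz <- function(x) x / (2 * pi * 1e6)

#' @rdname units
#' @export
ns_to_s <- function(x) x * 1e-9

#' @rdname units
#' @export
s_to_ns <- function(x) x * 1e9

#' @rdname units
#' @export
mhz_to_hz <- function(x) x * 1e6

#' @rdname units
#' @export
hz_to_mhz <- function(x) x / 1e6
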