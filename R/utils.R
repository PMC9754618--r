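#' Round half away from zero
#'
#' Deterministic decimal rounding with ties going up (towards +Inf for the
#' non-negative quantities handled here), as used for all printed tables:
#' ratios and rates to 2 decimals, scanpath distances to integers.
#' `base::round()` rounds half to even, which prints 5306.5 as 5306; the
#' tabulation convention here prints 5307.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(5306.5)   # 5307
#' round_half_up(0.615, 2) # 0.62
round_half_up <- function(x, digits = 0) {
  s <- x * 10^digits
  # guard against decimal literals sitting just below .5 in binary
  eps <- abs(s) * 1e-12 + 1e-12
  floor(s + 0.5 + eps) / 10^digits
}

#' Fixed-decimal formatting with half-up ties
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return character vector, every element with exactly `digits` decimals.
#' @export
#' @examples
#' format_fixed(c(2, 1.515), 2) # "2.00" "1.52"
format_fixed <- function(x, digits = 0) {
  out <- sprintf(paste0("%.", digits, "f"), round_half_up(x, digits))
  out[is.na(x)] <- NA_character_
  out
}

# FNV-1a 32-bit hash of a character scalar; used for config fingerprints in
# the run manifest (no cryptographic requirement).
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keeps h in double range
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403,
    # split so intermediates stay exactly representable in doubles
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  # h is a double in [0, 2^32); render as 8 hex digits
  hexd <- strsplit("0123456789abcdef", "")[[1]]
  paste(hexd[1 + (h %/% 16^(7:0)) %% 16], collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
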