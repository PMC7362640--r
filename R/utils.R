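#' @importFrom rlang .data
#' @import dplyr
#' @keywords internal
"_PACKAGE"

# Deterministic child seeds. Mixes the base seed with stream indexes so that
# independent stages (simulation, PFA runs, k-means cells) never share a
# stream; result always fits a 32-bit integer.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  primes <- c(7919, 104729, 1299709, 15485863)
  if (length(idx) > length(primes)) stop("too many seed indexes")
  x <- (abs(as.numeric(seed)) + sum(as.numeric(idx) * primes[seq_along(idx)])) %%
    2147483629
  as.integer(x) + 1L
}

# Length of stay in whole days; same-day discharge gives 0.
los_days <- function(admission, discharge) {
  as.integer(round(as.numeric(difftime(discharge, admission, units = "days"))))
}

# LOS guarded for use as a ratio denominator: same-day stays count as 1 day.
los_denominator <- function(los) pmax(los, 1)

split_codes <- function(x) strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)

join_codes <- function(lst) vapply(lst, paste, collapse = ";", FUN.VALUE = "")
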