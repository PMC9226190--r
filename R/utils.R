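# internal helpers shared across modules

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_format <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "binderid_format_error")
}

#' @noRd
#' Derive a per-component seed from a master seed so that independent
#' random streams (sequences, sampling, deamidation, intensities, ...)
#' do not reshuffle each other when one knob changes. Kept below 2^31.
sub_seed <- function(seed, component) {
  offsets <- c(sequence = 101L, sampling = 211L, deamidation = 307L,
               intensity = 401L, contaminant = 503L, reverse = 601L,
               score = 701L, bootstrap = 809L)
  off <- if (component %in% names(offsets)) offsets[[component]] else 997L
  as.integer((as.numeric(seed) * 48271 + off) %% 2147483647)
}

# split a protein/peptide string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

is_aa_string <- function(x, allow_x = FALSE) {
  alpha <- if (allow_x) c(AA20, "X") else AA20
  all(chars(x) %in% alpha)
}
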