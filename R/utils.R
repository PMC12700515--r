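# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Format a p-value the way clinical tables print it
#'
#' Two significant decimals, leading zero stripped, `"<.001"` below 0.001.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector.
#' @export
#' @examples
#' format_p(c(0.5270893, 0.0004, 0.02624887))
format_p <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  out <- ifelse(p < 0.001, "<.001", sub("^0\\.", ".", sprintf("%.2f", p)))
  out[is.na(p)] <- NA_character_
  out
}

# deterministic per-patient RNG sub-stream: seed derived from (seed, index, tag)
# so adding a patient never perturbs another patient's draws
.patient_seed <- function(seed, index, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  s <- (as.double(seed) %% 2147483647) + 1
  h <- (s * 48271 + index * 16807 + tag * 69621) %% 2147483647
  as.integer(h)
}

.set_stream <- function(seed, index, tag) {
  set.seed(.patient_seed(seed, index, tag))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# tiny FNV-1a hash over a character scalar, for config stamping
.hash_chr <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}
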