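# SAM flag bits (SAM spec section 1.4)
FLAG_PAIRED        <- 1L
FLAG_PROPER        <- 2L
FLAG_UNMAPPED      <- 4L
FLAG_MATE_UNMAPPED <- 8L
FLAG_REVERSE       <- 16L
FLAG_MATE_REVERSE  <- 32L
FLAG_FIRST         <- 64L
FLAG_SECOND        <- 128L
FLAG_SECONDARY     <- 256L
FLAG_QCFAIL        <- 512L
FLAG_DUPLICATE     <- 1024L
FLAG_SUPPLEMENTARY <- 2048L

has_flag <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Stable 31-bit polynomial string hash; used to derive per-sample RNG
# substreams so that changing cohort composition does not reshuffle the
# streams of unrelated samples. Arithmetic kept in doubles < 2^53.
stable_hash <- function(x) {
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 31 + code) %% 2147483629
  as.integer(h)
}

# Derive a child seed from a root seed and a string label, < 2^31.
derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) * 48271 + stable_hash(label)) %% 2147483629)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)
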