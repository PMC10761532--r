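# internal argument checks shared across modules

check_count <- function(x, what, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      abs(x - round(x)) > 1e-8) {
    stop(what, " must be a single integer", call. = FALSE)
  }
  if (x < min) {
    stop(what, " must be >= ", min, call. = FALSE)
  }
  as.numeric(round(x))
}

check_number <- function(x, what, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single number", call. = FALSE)
  }
  if (if (strict) x <= min else x < min) {
    stop(what, " must be ", if (strict) "> " else ">= ", min, call. = FALSE)
  }
  as.numeric(x)
}

# 32-bit FNV-1a over a string; cheap stable fingerprint for config provenance
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)  # xor touches low byte only
    # 32-bit modular multiply by the FNV prime, split to stay exact in doubles
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
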