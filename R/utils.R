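# small shared helpers

#' Round half away from zero
#'
#' Reporting rounding used in stocking-density tables (0.365 -> 0.37),
#' unlike base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

logit <- function(p) stats::qlogis(p)
invlogit <- function(x) stats::plogis(x)

# FNV-1a hash of a character scalar, as 8 hex digits; used to stamp outputs
# with a config fingerprint without external digest dependencies.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte only touches the low 8 bits
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    # 32-bit modular multiply by the FNV prime, split to stay exact in doubles
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# run code with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
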