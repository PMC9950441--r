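#' Derive a child seed from a master seed
#'
#' One master seed fans out to per-module seeds by a fixed integer
#' derivation so that each pipeline stage is independently reproducible.
#' The result always stays below 2^31.
#'
#' @param master integer master seed.
#' @param label character label of the consuming stage.
#' @return an integer seed.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- fnv1a32(paste0(label, ":", format(master, scientific = FALSE)))
  as.integer(h %% 2147483647)
}

# 32-bit FNV-1a hash of a character string, returned as a double in
# [0, 2^32). Used for seed derivation and config fingerprints; avoids an
# external digest dependency.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# xor for doubles holding 32-bit unsigned values
bitwXor_dbl <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

#' Fingerprint an R object
#'
#' Stable short hexadecimal fingerprint of a configuration object, attached
#' to every output table so results can be traced to the configuration that
#' produced them.
#'
#' @param x any R object that survives `deparse()`.
#' @return an 8-character hexadecimal string.
#' @export
config_hash <- function(x) {
  h <- fnv1a32(paste(deparse(x), collapse = "\n"))
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Standardize a variable within participant
#'
#' Centers and scales `x` separately for each participant, the convention
#' used for all `z_`-prefixed covariates in the mixed models (confidence and
#' movement onset are standardized per participant before entering any
#' model). Participants with zero variance get zeros.
#'
#' @param x numeric vector.
#' @param participant factor or vector of participant identifiers.
#' @return numeric vector of within-participant z-scores.
#' @export
zscore_by <- function(x, participant) {
  stopifnot(length(x) == length(participant))
  out <- ave(x, participant, FUN = function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  as.numeric(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
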