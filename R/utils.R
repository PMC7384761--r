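# Shared numeric and reproducibility helpers.

# Smallest P-value propagated anywhere; applied before log or quantile
# transforms so scores stay finite.
P_FLOOR <- 1e-300

floor_p <- function(p) pmax(p, P_FLOOR)

#' Derive a 32-bit-safe child seed from a master seed
#'
#' All randomness in multi-step protocols (sub-sampling, bootstraps) flows from
#' one master seed through this map, so replicates are independent but fully
#' reproducible and each derived seed stays below `2^31`.
#'
#' @param master Integer master seed.
#' @param ... Further non-negative integer indices (e.g. subsample size,
#'   replicate number).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in idx) {
    s <- (s * 1009 + as.double(k) * 101 + 7) %% 2147483647
  }
  as.integer(s)
}

# Stable content hash for provenance headers: FNV-1a over the serialized
# config text, hex-encoded. Avoids a digest dependency.
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (as.double(h) * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

`%||%` <- rlang::`%||%`
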