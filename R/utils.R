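# internal helpers

# linear-interpolation (type 7) quartiles; the pinned quantile convention
q_linear <- function(x, p) unname(stats::quantile(x, p, type = 7, na.rm = TRUE))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dd <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "deceptrf_error")))
}

# FNV-1a over the UTF-8 bytes of a string; used for config hashes in
# run manifests (stable, dependency-free; not cryptographic)
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648), b) + (h >= 2147483648) * 2147483648
    # 32-bit multiply split into 16-bit halves to stay exact in doubles
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

# deterministic JSON for artifacts: no timestamps, stable digits
write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
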