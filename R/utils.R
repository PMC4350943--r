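# Internal helpers: validation shorthands and deterministic seed fan-out.

stop_input <- function(msg, class = "sarsvr_error", ...) {
  abort(msg, class = c(class, "sarsvr_error"), ...)
}

check_number <- function(x, name, finite = TRUE, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    stop_input(sprintf("`%s` must be a single number.", name))
  }
  if (finite && !is.finite(x)) {
    stop_input(sprintf("`%s` must be finite.", name))
  }
  if (positive && x <= 0) {
    stop_input(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# 32-bit FNV-1a over a string, kept below 2^31 so the result is a valid R seed.
str_hash <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(x))) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% 2147483647)
}

# Derive a per-stage, per-dataset seed from one global seed so that re-running a
# single stage in isolation reproduces its in-study result.
derive_seed <- function(seed, stage, id = "") {
  as.integer((as.double(seed) * 48271 + str_hash(paste0(stage, "\r", id))) %% 2147483647)
}

# %.17g serialization: doubles survive a write/read round trip exactly and the
# formatted string is stable under re-serialization.
fmt_num <- function(x) sprintf("%.17g", x)
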