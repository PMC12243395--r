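# Internal helpers shared across modules.

# The five difficulty subscales, in canonical order. "antisocial" is the
# reverse-scored prosocial subscale (higher = greater difficulty).
SDQ_SUBSCALES <- c("emotional", "conduct", "hyperactivity", "peer", "antisocial")

# Item columns of a records table: item_01 .. item_25.
item_cols <- function() sprintf("item_%02d", 1:25)

# Default assignment of the 25 items to subscales. Items 21-25 are the raw
# prosocial items; they are reversed at scoring time, not here.
default_item_map <- function() {
  list(emotional = 1:5, conduct = 6:10, hyperactivity = 11:15,
       peer = 16:20, prosocial = 21:25)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a stream of child seeds from one master seed, each below 2^31.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
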