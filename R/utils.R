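
# Run expr under a temporary RNG state seeded with `seed`; NULL seed means
# use (and advance) the current RNG stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == round(x)

# frequencies live on a 0.5 Hz grid; guard against floating drift
.on_half_grid <- function(f, tol = 1e-9) abs(f * 2 - round(f * 2)) < tol
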