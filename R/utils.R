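#' @keywords internal
"_PACKAGE"

# Error helpers: every user-facing error carries a class so callers (and the
# CLI) can distinguish configuration problems from data problems.
oc_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "oncochrom_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

config_error    <- function(msg) oc_abort(msg, "oncochrom_config_error")
dimension_error <- function(msg) oc_abort(msg, "oncochrom_dimension_error")
validation_error <- function(msg) oc_abort(msg, "oncochrom_validation_error")
parse_error     <- function(msg) oc_abort(msg, "oncochrom_parse_error")
fit_error       <- function(msg) oc_abort(msg, "oncochrom_fit_error")
io_error        <- function(msg) oc_abort(msg, "oncochrom_io_error")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All generators funnel through this
# so that adding one generator never perturbs another.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# djb2-style rolling hash, reduced mod a Mersenne prime so doubles stay
# exact; deterministic and platform independent.
string_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\x1f")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

# Derive a named substream seed from a master seed.  Kept below 2^31-1.
substream_seed <- function(seed, name) {
  as.integer((as.numeric(seed) * 48271 + string_hash(name)) %% 2147483629)
}

# Stable hash of an R object via its JSON serialization (used for manifests).
config_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("%08x", string_hash(as.character(json)))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x > 0 && x == floor(x)

fmt_num <- function(x) {
  # shortest round-trippable-ish decimal; deterministic across runs
  sub("\\.?0+$", "", sprintf("%.10f", x))
}
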