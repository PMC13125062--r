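# Internal helpers: scoped RNG, delimited-table IO, small numerics.

# Save the current RNG state and seed a local stream. Pair with restore_rng()
# so package functions are deterministic given `seed` without clobbering the
# caller's RNG state. seed = NULL keeps the global stream (still restored-free).
local_rng <- function(seed) {
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  if (!is.null(seed)) set.seed(as.integer(seed))
  list(state = state, seeded = !is.null(seed))
}

restore_rng <- function(rng) {
  if (!rng$seeded) return(invisible(NULL))
  if (is.null(rng$state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", rng$state, envir = globalenv())
  }
  invisible(NULL)
}

# Derive a child seed from a base seed and a stream index; stays below 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 11 * stream) %% 2147483629
}

# Read a UTF-8 delimited table, auto-detecting comma vs tab from the header.
read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"", comment.char = "")
}

write_table_auto <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Pearson correlation that tolerates zero-variance input by returning NA.
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
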