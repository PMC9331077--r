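# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL means "use whatever stream is active".
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # initialise the stream so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a deterministic child seed from a base seed and an index, keeping the
# result in the 32-bit integer range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 1299709) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Named-vector lookup that recycles a scalar over requested names and
# validates that per-name mappings cover every requested name.
per_dose <- function(x, doses, what) {
  key <- format_dose(doses)
  if (length(x) == 1L && is.null(names(x))) {
    out <- rep(unname(x), length(doses))
    names(out) <- key
    return(out)
  }
  if (is.null(names(x))) {
    if (length(x) != length(doses)) {
      stop_fmt("`%s` must be scalar, named by dose, or have one value per dose", what)
    }
    names(x) <- key
    return(x)
  }
  missing <- setdiff(key, names(x))
  if (length(missing) > 0L) {
    stop_fmt("`%s` is missing values for dose(s): %s", what,
             paste(missing, collapse = ", "))
  }
  x[key]
}

format_dose <- function(dose) formatC(dose, format = "fg", big.mark = "")
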