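# internal helpers

# classed error so callers can distinguish failure modes programmatically
abort <- function(msg, class = "scdose_invalid_input", ...) {
  cond <- structure(
    class = c(class, "scdose_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

# evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards; seed = NULL means "use the current RNG stream"
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name))
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    abort(sprintf("`%s` = %g is outside its allowed range", name, x))
  invisible(x)
}

is_cell_table <- function(x) {
  is.data.frame(x) &&
    all(c("e0", "emax", "ec50_molar", "hill_slope") %in% names(x))
}
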