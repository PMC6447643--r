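# Internal helpers: structured errors, argument checks, seeded RNG.

fpact_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "fpact_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

check_positive <- function(x, name, class = "fpact_invalid_parameter") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    fpact_abort(sprintf("`%s` must be a single positive finite number", name),
                class)
  }
  invisible(x)
}

check_nonnegative <- function(x, name, class = "fpact_invalid_parameter") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    fpact_abort(sprintf("`%s` must be a single non-negative finite number", name),
                class)
  }
  invisible(x)
}

#' Derive a child RNG seed from a master seed
#'
#' Hierarchical seeding: each subject/acquisition gets a seed that depends
#' only on the master seed and its own index, so growing a cohort never
#' reshuffles earlier subjects. Values stay below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param index positive integer stream index.
#' @return an integer seed.
#' @export
derive_seed <- function(master, index) {
  m <- 2147483647
  s <- (as.numeric(master) %% m)
  # two rounds of a Lehmer-style mix keep distinct (master, index) pairs apart
  s <- (s * 48271 + as.numeric(index) * 16807 + 12345) %% m
  s <- (s * 69621 + 1013904223) %% m
  as.integer(s)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
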