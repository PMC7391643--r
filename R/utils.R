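# Shared small helpers: alphabets, seeded evaluation, validation.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA21 <- c(AA20, "X")
NT5 <- c("A", "C", "G", "T", "N")

#' Evaluate an expression with a fixed RNG state
#'
#' Runs `expr` after seeding R's RNG with `seed`, then restores the previous
#' RNG state, so stochastic operations are reproducible without leaking
#' global side effects.
#'
#' @param seed Integer seed (mandatory).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single non-missing number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# split a string into single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

# assert that a protein string uses only the 20 standard residues (+ X)
checkProtein <- function(s, what = "sequence", allowX = TRUE) {
  ok <- if (allowX) AA21 else AA20
  bad <- setdiff(unique(chars(s)), ok)
  if (length(bad))
    stop(sprintf("illegal residue(s) %s in %s", paste(bad, collapse = ","), what))
  invisible(TRUE)
}

# positions (1-based) of a character in a string
charPositions <- function(s, ch) {
  v <- chars(s)
  which(v == ch)
}

# derive a stream of sub-seeds from a master seed (kept below 2^31)
subSeed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + 97L * as.integer(k) %% 2147483L
}
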