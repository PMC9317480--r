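#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif binom.test
#' @importFrom utils read.delim write.table
NULL

# the 20 standard amino acids; X is tolerated as an ambiguity code
AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

.aa_ok <- function(s) {
  chars <- unique(strsplit(s, "")[[1]])
  all(chars %in% c(AA20, "X"))
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
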