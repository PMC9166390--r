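# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so callers' random streams are not
#' disturbed. With `seed = NULL` the expression runs on the current stream.
#' @noRd
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Derive k child seeds from a master seed (kept below 2^31).
spawn_seeds <- function(seed, k) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

BASES <- c("A", "C", "G", "T")

# Encode equal-length sequences as an integer matrix (rows = reads,
# cols = positions); A=1, C=2, G=3, T=4, N=5.
encode_reads <- function(x) {
  L <- unique(nchar(x))
  stopifnot(length(L) == 1L)
  codes <- integer(128)
  codes[utf8ToInt("A")] <- 1L
  codes[utf8ToInt("C")] <- 2L
  codes[utf8ToInt("G")] <- 3L
  codes[utf8ToInt("T")] <- 4L
  codes[utf8ToInt("N")] <- 5L
  v <- codes[utf8ToInt(paste(x, collapse = ""))]
  matrix(v, nrow = length(x), ncol = L, byrow = TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
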