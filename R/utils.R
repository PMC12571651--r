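# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats rnorm runif var
#' @importFrom utils head tail
NULL

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# evaluate `code` under a temporary RNG seed, restoring global RNG state after
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic 31-bit polynomial string hash (stable across platforms/sessions)
str_hash <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  h <- 0
  for (c in utf8ToInt(enc2utf8(s))) h <- (h * 31 + c) %% 2147483647
  h
}

# fold integers into one 31-bit seed; multiplier small enough that the
# intermediate product stays exact in double precision
mix_seed <- function(...) {
  h <- 17
  for (x in c(...)) {
    x <- if (is.character(x)) str_hash(x) else as.numeric(x) %% 2147483647
    h <- (h * 48271 + x) %% 2147483647
  }
  as.integer(h)
}

stop_shape <- function(what, expected, got) {
  stop(sprintf("%s: expected %s, got %s", what,
               paste(expected, collapse = "x"),
               paste(got, collapse = "x")), call. = FALSE)
}

as_row_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

relu <- function(x) pmax(x, 0)

# broadcast a length-h vector across K rows
rep_row <- function(v, K) matrix(v, nrow = K, ncol = length(v), byrow = TRUE)
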