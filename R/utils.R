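# internal helpers shared across modules

LN10 <- log(10)
UM2_TO_CM2 <- 1e-8  # 1 um^2 in cm^2

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate polynomial p0 + p1*z + ... at z (coefficients in increasing order)
polyEval <- function(coefs, z) {
  coefs <- unname(coefs)
  out <- rep(coefs[length(coefs)], length(z))
  for (k in rev(seq_len(length(coefs) - 1L)))
    out <- out * z + coefs[k]
  out
}

# derivative of the same polynomial at z
polyDeriv <- function(coefs, z) {
  d <- length(coefs) - 1L
  if (d < 1L) return(rep(0, length(z)))
  dc <- coefs[-1L] * seq_len(d)
  polyEval(dc, z)
}

# run code under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic numeric formatting for file output (>= 9 significant digits)
fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.9g", v)
  }, character(1))
  out
}

stopDomain <- function(...) stop(..., call. = FALSE)
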