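# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ng <- function(...) stop(..., call. = FALSE)

#' @noRd
assert_named_numeric <- function(x, what, nonneg = FALSE) {
  if (length(x) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (!is.numeric(x)) stop_ng(what, " must be numeric")
  nm <- names(x)
  if (is.null(nm) || any(nm == "") || anyNA(nm)) {
    stop_ng(what, " must have non-empty names")
  }
  if (anyDuplicated(nm)) stop_ng(what, " has duplicated labels: ",
                                 paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (anyNA(x)) stop_ng(what, " contains NA")
  if (nonneg && any(x < 0)) {
    stop_ng(what, " must be >= 0 (violated for: ",
            paste(nm[x < 0], collapse = ", "), ")")
  }
  x
}

# Deterministic substream seed derived from one user seed and a stream label.
# Keeps results reproducible while decoupling e.g. environment draws from
# phenotype draws. Always below 2^31.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

is_symmetric_matrix <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}

# FNV-1a hash of a character scalar; used to stamp output files with a
# config fingerprint without external digest dependencies.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

ng_message <- function(...) {
  if (isTRUE(getOption("nichegoal.verbose", FALSE))) message(...)
}
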