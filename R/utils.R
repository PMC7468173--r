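# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# symmetrize and check positive definiteness via Cholesky
check_spd <- function(m, name = deparse(substitute(m))) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(sprintf("`%s` must be a square matrix.", name))
  }
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
    abort(sprintf("`%s` must be symmetric.", name))
  }
  ok <- tryCatch({ chol(m); TRUE }, error = function(e) FALSE)
  if (!ok) abort(sprintf("`%s` is not positive definite (Cholesky failed).", name))
  (m + t(m)) / 2
}

is_whole <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < 1e-8)
}

# stable integer factor codes in order of first appearance of sorted keys
level_codes <- function(...) {
  key <- do.call(paste, c(list(...), sep = "\r"))
  match(key, sort(unique(key)))
}
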