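`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a temporarily seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

as_binary <- function(mask, arg = "mask") {
  m <- as.matrix(mask)
  if (!all(m %in% c(0, 1)))
    stop(sprintf("'%s' must be binary {0,1}; found other values", arg))
  storage.mode(m) <- "integer"
  m
}

check_same_shape <- function(a, b, na = "a", nb = "b") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch: %s is %s, %s is %s",
                 na, paste(dim(a), collapse = "x"),
                 nb, paste(dim(b), collapse = "x")))
  invisible(TRUE)
}

# 90-degree counter-clockwise rotation: new[i,j] = old[j, W+1-i] (1-based)
rot90ccw <- function(m) {
  r <- t(m)
  r[rev(seq_len(nrow(r))), , drop = FALSE]
}

rot_k <- function(m, k) {
  k <- k %% 4L
  for (i in seq_len(k)) m <- rot90ccw(m)
  m
}

# small stable FNV-1a hash of a character string, for output provenance
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h %% 2^31, b) + (h - h %% 2^31)  # xor low bits only
    # h * 16777619 mod 2^32, split to stay within double precision
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
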