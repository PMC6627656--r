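# Neighbor shifts under reflected (homogeneous Neumann) boundaries.
# shift_xm(m)[y, x] == m[y, x-1], with the out-of-bounds neighbor replaced
# by the boundary pixel itself (half-sample reflection). Rows are y
# (top-down), columns are x.
shift_xm <- function(m) m[, c(1L, seq_len(ncol(m) - 1L)), drop = FALSE]
shift_xp <- function(m) m[, c(seq_len(ncol(m) - 1L) + 1L, ncol(m)), drop = FALSE]
shift_ym <- function(m) m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE]
shift_yp <- function(m) m[c(seq_len(nrow(m) - 1L) + 1L, nrow(m)), , drop = FALSE]

stop_dim <- function(msg) stop(errorCondition(msg, class = c("radusm_dim_error", "error")))
stop_fmt <- function(msg) stop(errorCondition(msg, class = c("radusm_format_error", "error")))
stop_range <- function(msg) stop(errorCondition(msg, class = c("radusm_range_error", "error")))

check_same_dim <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop_dim(sprintf("%s must have identical dimensions (%d x %d vs %d x %d)",
                     what, nrow(a), ncol(a), nrow(b), ncol(b)))
}

# evaluate f() with the RNG seeded, restoring the caller's RNG state after
with_seed <- function(seed, f) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  f()
}
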