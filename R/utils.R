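#' @keywords internal
"_PACKAGE"

## Internal validation helpers ------------------------------------------------

stop_named <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "vertebrotwin_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         finite = TRUE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop_named("validation_error", "'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stop_named("validation_error", "'%s' = %g outside [%g, %g]", name, x, lower, upper)
  if (integer && x != round(x))
    stop_named("validation_error", "'%s' must be an integer", name)
  invisible(x)
}

check_fraction <- function(x, name) check_scalar(x, name, 0, 1)

## Deterministic seed splitting.
## All randomness flows from one master seed; each module/stage derives its own
## stream with split_seed(master, label[, counter]) so stages can be re-run
## standalone with identical results. 32-bit arithmetic done in doubles
## (exact below 2^53), result kept in [1, 2^31 - 2].
split_seed <- function(seed, label, counter = 0L) {
  check_scalar(seed, "seed", integer = TRUE)
  h <- 17
  for (b in utf8ToInt(paste0(label, "#", counter)))
    h <- (h * 31 + b) %% 2147483647
  out <- (abs(seed) * 48271 + h) %% 2147483647
  as.integer(out) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

vnorm <- function(v) sqrt(sum(v * v))

rownorms <- function(m) sqrt(rowSums(m * m))

## Rodrigues rotation matrix sending unit vector a to unit vector b
rotation_between <- function(a, b) {
  a <- a / vnorm(a); b <- b / vnorm(b)
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (vnorm(v) < 1e-12) {
    if (c_ > 0) return(diag(3))
    ## opposite: rotate pi about any axis orthogonal to a
    axis <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- axis - sum(axis * a) * a
    axis <- axis / vnorm(axis)
    return(rotation_axis_angle(axis, pi))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

rotation_axis_angle <- function(axis, angle) {
  axis <- axis / vnorm(axis)
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  c_ <- cos(angle); s <- sin(angle); t <- 1 - c_
  matrix(c(t * x * x + c_,     t * x * y + s * z, t * x * z - s * y,
           t * x * y - s * z,  t * y * y + c_,    t * y * z + s * x,
           t * x * z + s * y,  t * y * z - s * x, t * z * z + c_),
         3, 3)
}
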