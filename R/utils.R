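`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, msg, ...) {
  if (cond) stop(sprintf(msg, ...), call. = FALSE)
}

#' Intensity channel name for a (wavelength, separation) pair
#'
#' Raw worksheets name their intensity columns `i_{wavelength}nm_{sep}cm`,
#' e.g. `i_730nm_3cm`.
#'
#' @param wavelength_nm wavelength in nm
#' @param separation_cm source-detector separation in cm
#' @return character vector of column names
#' @export
channel_name <- function(wavelength_nm, separation_cm) {
  sprintf("i_%gnm_%gcm", wavelength_nm, separation_cm)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Linear interpolation across runs of NA no longer than max_gap samples;
# longer runs are left missing.
fill_short_gaps <- function(x, max_gap) {
  if (!anyNA(x) || max_gap <= 0) return(x)
  n <- length(x)
  idx <- which(is.na(x))
  runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  ok <- which(!is.na(x))
  if (length(ok) < 2) return(x)
  for (r in runs) {
    if (length(r) > max_gap) next
    if (min(r) == 1L || max(r) == n) next  # cannot interpolate at the edges
    x[r] <- approx(ok, x[ok], xout = r)$y
  }
  x
}
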