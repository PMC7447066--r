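`%||%` <- function(a, b) if (is.null(a)) b else a

## xyz-vector columns for atom indices (bio3d flat convention x1,y1,z1,x2,...)
xyz_cols <- function(i) rep((as.integer(i) - 1L) * 3L, each = 3L) + seq_len(3L)

## row-wise Euclidean norms of an n x 3 matrix
row_norms <- function(m) sqrt(rowSums(m * m))

unit_rows <- function(m, fallback = c(0, 0, 1)) {
  n <- row_norms(m)
  bad <- n < 1e-12
  n[bad] <- 1
  out <- m / n
  if (any(bad)) out[bad, ] <- matrix(fallback, sum(bad), 3, byrow = TRUE)
  out
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

abort <- function(...) stop(..., call. = FALSE)

## descriptive mean/sd/sem helpers; sd_type switches sample vs population
spread_sd <- function(x, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  n <- length(x)
  if (n < 2) return(0)
  if (sd_type == "sample") stats::sd(x)
  else sqrt(sum((x - mean(x))^2) / n)
}
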