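# Independent oracles used across test files. These deliberately do not
# share code with the package implementation.

# even-odd ray-crossing point-in-polygon test
pip_oracle <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  for (q in seq_along(px)) {
    cross <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((vy[i] > py[q]) != (vy[j] > py[q]) &&
          px[q] < (vx[j] - vx[i]) * (py[q] - vy[i]) / (vy[j] - vy[i]) +
            vx[i])
        cross <- !cross
      j <- i
    }
    inside[q] <- cross
  }
  inside
}

# coverage dose by explicit descending sort (integer-rank cases only)
d80_oracle <- function(values, coverage = 0.8) {
  r <- coverage * length(values)
  stopifnot(abs(r - round(r)) < 1e-12)
  sort(values, decreasing = TRUE)[round(r)]
}

# quick volume builder
vol3 <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                 modality = "CT") {
  image_volume(data, spacing = spacing, origin = origin,
               modality = modality)
}
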