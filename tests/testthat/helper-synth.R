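# shared fixture builders; everything is generated in code at test time

# small fast config for unit tests
tinyConfig <- function(seed = 1L, ...) {
  synthConfig(seed = seed, n_pairs = 1, grid_rows = 4, grid_cols = 4,
              soma_row = 2, soma_col = 2, ...)
}

# an averaged trace: signal plus the mean of `reps` independent noise draws
avgTrace <- function(signal, reps = 4, noiseSd = 3) {
  if (noiseSd == 0 || reps == 0) return(signal)
  signal + rowMeans(matrix(rnorm(length(signal) * reps, 0, noiseSd),
                           ncol = reps))
}

# standard synthetic components at 10 kHz used across event-module tests
DT <- 0.1
STIM_ON <- 10
synKernel <- function(amp = 60, onset = STIM_ON + 7, len = 150)
  makeEpscKernel(amp, 2, 15, onset, DT, len)
dirKernel <- function(amp = 150, onset = STIM_ON + 2, len = 150)
  makeEpscKernel(amp, 0.3, 3, onset, DT, len)

# hand-built InputMap on a regular grid (row 1 pia-ward)
mkMap <- function(values, mask = NULL, px = c(50, 50), origin = c(0, 150),
                  soma = c(NA_real_, NA_real_), frame = "slice",
                  meta = list()) {
  values <- as.matrix(values)
  if (is.null(mask)) {
    mask <- matrix("valid", nrow(values), ncol(values))
    mask[is.na(values)] <- "unsampled"
  }
  new("InputMap", values = values, mask = mask, pixelSize = px,
      frame = frame, origin = origin, soma = soma, meta = meta)
}
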