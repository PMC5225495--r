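# Shared fixture builders; everything is generated in code.

TR <- 2.638

# Single- or multi-node sinusoid panel at the study TR.
sinePanel <- function(freqs, n = 500, tr = TR, amp = 1, phase = 0) {
  tt <- (seq_len(n) - 1) * tr
  rows <- mapply(function(f, a, ph) a * cos(2 * pi * f * tt + ph),
                 freqs, rep_len(amp, length(freqs)),
                 rep_len(phase, length(freqs)), SIMPLIFY = FALSE)
  timeSeriesPanel(list(do.call(rbind, rows)), trSeconds = tr)
}

# Random covariate table with a given group layout.
makeCohort <- function(groups) {
  n <- length(groups)
  data.frame(
    subject_id = sprintf("sub_%03d", seq_len(n)),
    group = groups,
    age = rnorm(n, 65, 8),
    sex = rbinom(n, 1, 0.5),
    headcoil = rbinom(n, 1, 0.7),
    motion = rlnorm(n, log(0.1), 0.4)
  )
}

# Interior-point index range (drop `edge` points from both ends).
interior <- function(n, edge) (edge + 1):(n - edge)
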