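# shared fixtures built in code

uniform_frames <- function(n, h = 8, w = 8, value = c(50, 50, 50)) {
  f <- array(0, c(h, w, 3))
  for (ch in 1:3) f[, , ch] <- value[ch]
  replicate(n, f, simplify = FALSE)
}

# brute-force Euclidean match counter, independent of the package's path
oracle_count <- function(value, samples, radius) {
  n <- 0L
  for (s in seq_len(nrow(samples))) {
    if (sqrt(sum((samples[s, ] - value)^2)) < radius) n <- n + 1L
  }
  n
}

# per-pixel confusion tally by explicit looping
oracle_confusion <- function(mask, truth) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    m <- mask[i, j]; g <- truth[i, j]
    if (m && g) tp <- tp + 1L else if (m && !g) fp <- fp + 1L
    else if (!m && g) fn <- fn + 1L else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# foreground recall of the crossing object inside the old footprint,
# aggregated over frames where the object overlaps it
crossing_recall <- function(seg, seq) {
  q <- attr(seq, "old_footprint")
  cm <- attr(seq, "crossing_masks")
  tp <- fn <- 0L
  for (t in seq_along(cm)) {
    ov <- cm[[t]] & q
    if (!any(ov)) next
    tp <- tp + sum(seg$masks[[t]][ov])
    fn <- fn + sum(!seg$masks[[t]][ov])
  }
  tp / (tp + fn)
}
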