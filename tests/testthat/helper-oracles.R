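# Brute-force sample-wise reference detector: supra-threshold runs >= min
# duration, boundaries extended to the boundary crossing, events closer
# than the merge gap combined. Written independently of the package's
# run-length implementation (explicit while-loops over samples).
naive_ripple_detector <- function(env, rate, periods, thresh = 3, boundary = 1,
                                  min_ms = 15, merge_ms = 40) {
  min_n <- max(1, round(min_ms / 1000 * rate))
  gap_n <- round(merge_ms / 1000 * rate)
  out <- list()
  for (k in seq_len(nrow(periods))) {
    i0 <- max(1, floor(periods$start_s[k] * rate) + 1)
    i1 <- min(length(env), ceiling(periods$end_s[k] * rate))
    cand <- list()
    i <- i0
    while (i <= i1) {
      if (env[i] > thresh) {
        j <- i
        while (j < i1 && env[j + 1] > thresh) j <- j + 1
        if (j - i + 1 >= min_n) cand[[length(cand) + 1]] <- c(i, j)
        i <- j + 1
      } else i <- i + 1
    }
    # extend each to the boundary crossings inside the period
    cand <- lapply(cand, function(ab) {
      a <- ab[1]; b <- ab[2]
      while (a > i0 && env[a - 1] > boundary) a <- a - 1
      while (b < i1 && env[b + 1] > boundary) b <- b + 1
      c(a, b)
    })
    # merge events closer than the gap
    if (length(cand)) {
      merged <- list(cand[[1]])
      for (c2 in cand[-1]) {
        last <- merged[[length(merged)]]
        if (c2[1] - last[2] - 1 < gap_n) {
          merged[[length(merged)]] <- c(last[1], max(last[2], c2[2]))
        } else merged[[length(merged) + 1]] <- c2
      }
      for (m in merged) out[[length(out) + 1]] <-
          data.frame(start = m[1], end = m[2])
    }
  }
  do.call(rbind, out)
}
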