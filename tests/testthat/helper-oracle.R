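# Independent brute-force oracle for the windowed cross-correlation search:
# a plain loop over every candidate offset using stats::cor, with the same
# documented tie-breaks (nearest the prediction, then more rostral).

oracleCorrAt <- function(values, patternSamples, center) {
  v <- values
  v[is.na(v)] <- 0
  w <- v[(center - 5):(center + 5)]
  if (stats::sd(w) < 1e-12 || stats::sd(patternSamples) < 1e-12) return(0)
  stats::cor(w, patternSamples)
}

oracleWindowedArgmax <- function(values, patternSamples, positions,
                                 probMm, halfwidthMm) {
  n <- length(values)
  cand <- which(positions >= probMm - halfwidthMm &
                positions <= probMm + halfwidthMm)
  cand <- cand[cand > 5 & cand <= n - 5]
  if (!length(cand)) return(NULL)
  sc <- vapply(cand, function(i) oracleCorrAt(values, patternSamples, i),
               numeric(1))
  best <- cand[sc >= max(sc) - 1e-12]
  d <- abs(positions[best] - probMm)
  best <- best[d <= min(d) + 1e-12]
  list(positionMm = positions[best[1]], maxCorr = max(sc))
}
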