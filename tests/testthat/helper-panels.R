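# A 10-locus panel with planted QC failures: one locus below the MAF
# threshold, one above the missing-rate threshold, one gross HWE
# violation (no heterozygotes).
make_qc_panel <- function() {
  set.seed(99)
  n <- 400
  X <- sapply(1:7, function(j) rbinom(n, 2, 0.3))
  rare <- c(rep(1, 3), rep(0, n - 3))            # MAF 3/800 < 0.01
  missing <- rbinom(n, 2, 0.3)
  missing[1:40] <- NA                            # missing rate 0.1 > 0.05
  hwe_bad <- rep(c(0, 2), n / 2)                 # no heterozygotes
  X <- cbind(X, rare = rare, missing = missing, hwe_bad = hwe_bad)
  colnames(X) <- paste0("s", 1:10)
  X
}
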