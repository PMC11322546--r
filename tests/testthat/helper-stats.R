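# Enumeration oracle for the two-sided rank-sum p of two small groups:
# every assignment of group labels to the pooled ranks is enumerated.
enumRankSumP <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  us <- apply(idx, 2L, function(i) sum(r[i]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(us <= uObs), mean(us >= uObs)))
}

mkRecords <- function(vals1, vals2, genotypes = c("wt", "mut"),
                      timepoint = 14) {
  data.frame(
    genotype = rep(genotypes, c(length(vals1), length(vals2))),
    timepoint_d = timepoint,
    height_um = c(vals1, vals2),
    experiment_id = "e1")
}
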