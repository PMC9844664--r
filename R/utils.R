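# Deterministic per-replicate substream seed: a counter-indexed congruential
# hash of the master seed, kept inside the 32-bit signed range so B can grow
# without reshuffling earlier replicates.
.substream_seed <- function(seed, counter) {
  m <- 2147483647
  s <- (as.double(seed) %% m) * 48271 + as.double(counter) * 1009 + 17
  as.integer(s %% m) + 1L
}

.upper_pairs <- function(labels) {
  p <- length(labels)
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             node_i = labels[idx[, 1]], node_j = labels[idx[, 2]],
             stringsAsFactors = FALSE)
}

.as_values_matrix <- function(data) {
  if (inherits(data, "symptom_dataset")) data$values else as.matrix(data)
}
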