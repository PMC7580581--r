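# fixtures built in code: no data files

# random sparse non-negative abundance matrix with no all-zero rows
rand_abundance <- function(n, m, seed, sparsity = 0.4,
                           unit_state = "raw") {
  set.seed(seed)
  vals <- matrix(stats::rexp(n * m, rate = 0.1), n, m)
  vals[matrix(stats::runif(n * m) < sparsity, n, m)] <- 0
  zero_rows <- rowSums(vals) == 0
  vals[zero_rows, 1] <- 1
  dimnames(vals) <- list(sprintf("s%02d", seq_len(n)),
                         sprintf("c%02d", seq_len(m)))
  abundance_matrix(vals, unit_state)
}

# Euclidean distance matrix from a coordinate matrix
euclid_D <- function(X) {
  if (is.null(rownames(X))) rownames(X) <- sprintf("p%02d", seq_len(nrow(X)))
  distance_matrix(as.matrix(stats::dist(X)))
}

# small two-colony mother/pup metadata table
toy_metadata <- function() {
  data.frame(
    sample_id = c("m1", "p1", "m2", "p2"),
    colony = c("SSB", "SSB", "FWB", "FWB"),
    age_class = c("mother", "pup", "mother", "pup"),
    family_id = c("F1", "F1", "F2", "F2"),
    stringsAsFactors = FALSE)
}
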