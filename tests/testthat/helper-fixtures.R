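# Shared fixtures built in code.

# labeled dataset with unique keys, no chemistry involved
make_labeled <- function(labels, concern = NULL, prefix = "k") {
  n <- length(labels)
  data.frame(key = paste0(prefix, seq_len(n)),
             std_smiles = paste0("S", seq_len(n)),
             concern = if (is.null(concern)) {
               ifelse(labels == 1L, "most", "no")
             } else concern,
             label = labels, stringsAsFactors = FALSE)
}

# tiny binary fingerprint matrix from lists of set bit positions
make_fp <- function(bit_sets, nbits = 16L) {
  m <- matrix(0, nrow = length(bit_sets), ncol = nbits,
              dimnames = list(names(bit_sets), paste0("b", seq_len(nbits))))
  for (i in seq_along(bit_sets)) m[i, bit_sets[[i]]] <- 1
  m
}

# brute-force chi-squared statistic: sum (O - E)^2 / E over the table
chisq_brute <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# exhaustive Youden-J scan used as the threshold oracle
youden_brute <- function(scores, labels) {
  cuts <- sort(unique(scores))
  j <- sapply(cuts, function(cut) {
    mean(scores[labels == 1] >= cut) - mean(scores[labels == 0] >= cut)
  })
  max(cuts[j >= max(j) - 1e-12])
}
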