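# Random fixtures used by the property-style tests.

`%||%` <- function(x, y) if (is.null(x)) y else x

random_positive_counts <- function(max = 50) {
  repeat {
    k <- sample.int(max, 3, replace = TRUE) - 1L
    if (sum(k) >= 1) return(positive_counts(k[1], k[2], k[3]))
  }
}

# counts suitable for both kappas and the logit method: d >= 1 and b+c >= 1
random_nondegenerate_counts <- function(max = 50) {
  positive_counts(sample.int(max, 1), sample.int(max, 1), sample.int(max, 1))
}

random_clusters <- function(n_patients = 8, max = 6) {
  repeat {
    b <- sample.int(max + 1, n_patients, replace = TRUE) - 1L
    c <- sample.int(max + 1, n_patients, replace = TRUE) - 1L
    d <- sample.int(max + 1, n_patients, replace = TRUE) - 1L
    if (sum(b + c + d) >= 1) {
      return(clustered_findings(sprintf("p%02d", seq_len(n_patients)),
                                b = b, c = c, d = d))
    }
  }
}
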