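# Independent oracles used across tests. These deliberately use naive
# algorithms (BFS flood fill, exhaustive pairwise comparison, enumeration)
# so they share no code with the implementation they check.

# flood-fill connected components with an explicit neighbourhood offset list
flood_fill_components <- function(mask, offsets) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  nxt <- 0L
  idx_all <- which(mask != 0)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      co <- arrayInd(v, dims)
      for (k in seq_len(nrow(offsets))) {
        nb <- co + offsets[k, ]
        if (any(nb < 1) || any(nb > dims)) next
        j <- nb[1] + dims[1] * (nb[2] - 1) + dims[1] * dims[2] * (nb[3] - 1)
        if (mask[j] != 0 && lab[j] == 0L) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

offsets_6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))

# brute-force ROC AUC: all positive/negative pairs, ties 1/2
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# a small labelled phantom shared by several test files
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_phantom(phantom_config(
        n_rim_pos = 4L, n_rim_neg = 8L, n_artefacts = 1L, seed = 99L))
    cache
  }
})

labelled_candidates <- function(ph) {
  label_candidates(
    extract_components(ph$lesion_mask != 0, ph$spacing_mm,
                       patient_id = "P1", site_id = "A"),
    ph$rim_pos_mask)
}
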