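## Small generators shared across test files.

random_community <- function(n_sites, n_families, seed, max_count = 20,
                             p_zero = 0.3) {
  with_seed(seed, {
    m <- matrix(stats::rbinom(n_sites * n_families, 1, 1 - p_zero) *
                  sample.int(max_count, n_sites * n_families, replace = TRUE),
                n_sites, n_families)
    community_matrix(m,
                     site_ids = paste0("s", seq_len(n_sites)),
                     family_ids = paste0("fam", seq_len(n_families)))
  })
}

random_traits <- function(families, seed) {
  with_seed(seed,
            trait_table(stats::setNames(sample(FFG_LABELS, length(families),
                                               replace = TRUE), families)))
}

## brute-force loop-sum of a biotic index, kept deliberately naive and
## independent of compute_index_score()
loop_sum_score <- function(present, scores) {
  total <- 0L
  for (f in unique(present)) {
    for (g in names(scores)) {
      if (identical(f, g)) total <- total + scores[[g]]
    }
  }
  total
}
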