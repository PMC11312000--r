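# Independent brute-force oracle for the 2xK Fisher exact test: recursive
# enumeration of first rows with exact choose() ratios (no log-space, no
# shared code with the package implementation).
oracle_fisher_2xk <- function(tab) {
  tab <- as.matrix(tab)
  cs <- colSums(tab)
  r1 <- sum(tab[1L, ])
  n <- sum(tab)
  prob_row <- function(a) prod(choose(cs, a)) / choose(n, r1)
  p_obs <- prob_row(tab[1L, ])
  total <- 0
  rec <- function(j, remaining, acc) {
    if (j > length(cs)) {
      if (remaining == 0) {
        p <- prob_row(acc)
        if (p <= p_obs * (1 + 1e-7)) total <<- total + p
      }
      return(invisible(NULL))
    }
    for (a in 0:min(cs[j], remaining)) {
      rec(j + 1L, remaining - a, c(acc, a))
    }
  }
  rec(1L, r1, integer(0))
  min(total, 1)
}

# Build a one-sample nucleus tibble from a named vector of
# token-string -> nucleus count, padding with normal diploid nuclei.
make_nuclei <- function(counts, n_total = 100, sample_id = "s1") {
  toks <- rep(names(counts), counts)
  if (length(toks) < n_total) {
    toks <- c(toks, rep("O+G;O+G", n_total - length(toks)))
  }
  tibble::tibble(sample_id = sample_id,
                 nucleus_id = sprintf("n%03d", seq_along(toks)),
                 tokens = toks,
                 split_ok = NA_integer_)
}

# Classify + summarize one sample in a single step.
summarize_counts <- function(counts, n_total = 100, ...) {
  summarize_fish_sample(classify_nuclei(make_nuclei(counts, n_total)), ...)
}

# The contingency table of the reference pattern distribution.
reference_pattern_table <- function() {
  rbind(discordant = c(12, 14, 3), concordant = c(137, 30, 1))
}
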