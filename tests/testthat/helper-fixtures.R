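# Shared helpers: small random score tables, IoU, packaged count fixtures.

iou <- function(a, b) sum(a & b) / sum(a | b)

# random pair of small score samples (combined n <= n_max)
random_score_pair <- function(n_max = 14) {
  n1 <- sample(seq_len(n_max - 1), 1)
  n2 <- sample(seq_len(n_max - n1), 1)
  list(x = sample(0:5, n1, replace = TRUE),
       y = sample(0:5, n2, replace = TRUE))
}

scores_to_table <- function(scores, genotype = "g") {
  cnt <- tabulate(factor(as.character(scores), levels = as.character(0:5)),
                  nbins = 6)
  score_table(genotype, cnt)
}

valium1_fixture <- function() {
  system.file("extdata", "valium1_counts.csv", package = "modscreen")
}

valium20_fixture <- function() {
  system.file("extdata", "valium20_counts.csv", package = "modscreen")
}

luciferase_table <- function() score_table("Luciferase", c(0, 5, 20, 35, 7, 0))
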