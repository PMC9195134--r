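# Independent oracles and fixture builders used across the suite.

# Zooming grid search over (log a, b) minimizing the original-scale RSS of
# y = a*exp(b*x). Independent of the package's optimizer: it shares only
# the log-linear OLS starting region.
grid_search_rss <- function(x, y, n_grid = 41L, zoom = 5L) {
  pos <- y > 0
  ols <- stats::lm.fit(cbind(1, x[pos]), log(y[pos]))
  la <- ols$coefficients[[1L]]
  b <- ols$coefficients[[2L]]
  la_w <- max(abs(la) * 0.5, 0.5)
  b_w <- max(abs(b) * 0.5, 0.05)
  best <- c(la = la, b = b)
  best_rss <- Inf
  for (z in seq_len(zoom)) {
    las <- seq(best[["la"]] - la_w, best[["la"]] + la_w, length.out = n_grid)
    bs <- seq(best[["b"]] - b_w, best[["b"]] + b_w, length.out = n_grid)
    for (lai in las) {
      # vectorized over the b grid
      rss <- vapply(bs, function(bi) sum((y - exp(lai + bi * x))^2),
                    numeric(1L))
      k <- which.min(rss)
      if (rss[k] < best_rss) {
        best_rss <- rss[k]
        best <- c(la = lai, b = bs[k])
      }
    }
    la_w <- la_w * 2.5 / n_grid
    b_w <- b_w * 2.5 / n_grid
  }
  list(rss = best_rss, a = exp(best[["la"]]), b = best[["b"]])
}

# Build a small five-gene alignment set in code. Each strain's sequence is
# the gene's ancestral sequence with a few deterministic substitutions so
# pairwise distances are small but nonzero.
make_gene_set <- function(strains = c("strainA", "strainB", "strainC"),
                          lengths = c(atpD = 300, gyrB = 450, recA = 300,
                                      rpoB = 600, trpB = 300),
                          seed = 42) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  genes <- lapply(names(lengths), function(g) {
    anc <- sample(bases, lengths[[g]], replace = TRUE)
    seqs <- vapply(seq_along(strains), function(i) {
      s <- anc
      # i-1 substitutions per 100 sites, cycling through the other bases
      nmut <- (i - 1L) * lengths[[g]] %/% 100L
      if (nmut > 0L) {
        at <- sample(lengths[[g]], nmut)
        s[at] <- vapply(s[at], function(ch) {
          sample(setdiff(bases, ch), 1L)
        }, character(1L))
      }
      paste(s, collapse = "")
    }, character(1L))
    names(seqs) <- strains
    seqs
  })
  names(genes) <- names(lengths)
  gene_alignment_set(genes)
}

write_gene_fastas <- function(set, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  paths <- vapply(MLSA_GENES, function(g) {
    p <- file.path(dir, paste0(g, ".fasta"))
    seqs <- set$genes[[g]]
    writeLines(paste0(">", names(seqs), "\n", seqs), p)
    p
  }, character(1L))
  paths
}
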