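test_that("alignment-set validation enforces the MLSA scheme invariants", {
  set <- make_gene_set(strains = "s1")
  expect_s3_class(set, "gene_alignment_set")
  expect_equal(set$strains, "s1")
  expect_equal(names(set$genes), MLSA_GENES)

  genes <- make_gene_set()$genes
  # unequal lengths within a gene
  broken <- genes
  broken$atpD[["strainB"]] <- substr(broken$atpD[["strainB"]], 1, 299)
  expect_error(gene_alignment_set(broken), "alignment error in gene atpD")
  # out-of-frame length
  broken <- genes
  broken$gyrB[] <- paste0(broken$gyrB, "A")
  expect_error(gene_alignment_set(broken), "frame error in gene gyrB")
  # strain missing from one gene
  broken <- genes
  broken$trpB <- broken$trpB[c("strainA", "strainB")]
  expect_error(gene_alignment_set(broken), "membership error")
  # wrong gene roster
  expect_error(gene_alignment_set(genes[1:4]), "five genes")
})

test_that("concatenation is head-to-tail in the fixed gene order", {
  set <- make_gene_set(strains = c("s1", "s2"))
  cc <- concatenate_mlsa(set)
  expect_equal(unname(nchar(cc)), c(1950L, 1950L))  # 300+450+300+600+300
  expect_equal(substr(cc[["s1"]], 1, 300), set$genes$atpD[["s1"]])
  expect_equal(substr(cc[["s1"]], 301, 750), set$genes$gyrB[["s1"]])
  expect_equal(substr(cc[["s1"]], 1651, 1950), set$genes$trpB[["s1"]])
  expect_error(concatenate_mlsa(set, "nope"), "unknown strain")
})

test_that("site classification distinguishes transitions, transversions and excluded sites", {
  a <- paste(rep("A", 100), collapse = "")
  expect_equal(unclass(classify_sites(a, a)),
               list(compared = 100L, transitions = 0L, transversions = 0L,
                    excluded = 0L), ignore_attr = TRUE)

  # 4 A<->G changes and 2 A<->T changes in 100 sites
  b <- a
  substr(b, 1, 4) <- "GGGG"
  substr(b, 11, 12) <- "TT"
  cmp <- classify_sites(a, b)
  expect_equal(cmp$transitions, 4L)
  expect_equal(cmp$transversions, 2L)
  expect_equal(cmp$compared, 100L)

  # pairwise deletion: a gap column is excluded, not counted as change
  x <- "ACGTACGTAA"
  y <- "-CGTACGTAG"   # gap at site 1, A->G transition at site 10
  cmp <- classify_sites(y, x)
  expect_equal(cmp$compared, 9L)
  expect_equal(cmp$excluded, 1L)
  expect_equal(cmp$transitions, 1L)
  expect_equal(cmp$transversions, 0L)

  # case-insensitive, U read as T, ambiguity codes excluded
  cmp <- classify_sites("acgu", "ACGT")
  expect_equal(cmp$compared, 4L)
  expect_equal(cmp$transitions + cmp$transversions, 0L)
  cmp <- classify_sites("NCGT", "ACGT")
  expect_equal(cmp$excluded, 1L)

  expect_error(classify_sites("ACGT", "ACG"), "lengths differ")
})

test_that("K2P distance matches hand-computed closed-form values", {
  # -1/2 * log(0.90 * sqrt(0.96)) at P = 0.04, Q = 0.02
  expect_equal(k2p_from_proportions(0.04, 0.02), 0.0628857565, tolerance = 1e-8)
  # one transition among nine compared sites: -1/2 * log(7/9)
  expect_equal(k2p_from_proportions(1 / 9, 0), 0.1256572141, tolerance = 1e-8)
  expect_equal(k2p_from_proportions(0, 0), 0)

  a <- paste(rep("A", 100), collapse = "")
  b <- a
  substr(b, 1, 4) <- "GGGG"
  substr(b, 11, 12) <- "TT"
  expect_equal(k2p_distance(classify_sites(a, b)), 0.0628857565,
               tolerance = 1e-8)

  expect_error(k2p_from_proportions(0.5, 0.1), "saturation")
  expect_error(k2p_from_proportions(0.1, 0.5), "saturation")
  expect_error(k2p_distance(classify_sites("----", "ACGT")), "no overlapping")
})

test_that("the K2P correction never shrinks the raw mismatch proportion", {
  set.seed(11)
  for (i in 1:200) {
    p <- runif(1, 0, 0.4)
    q <- runif(1, 0, min(0.45, (1 - 2 * p) * 0.95))
    if (2 * p + q >= 1 || 2 * q >= 1) next
    expect_gte(k2p_from_proportions(p, q), p + q)
  }
})

test_that("distance on the concatenation equals distance from pooled per-gene counts", {
  set <- make_gene_set(strains = c("s1", "s2", "s3"), seed = 7)
  cc <- concatenate_mlsa(set)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    whole <- classify_sites(cc[[pair[1]]], cc[[pair[2]]])
    per_gene <- lapply(set$genes, function(g)
      classify_sites(g[[pair[1]]], g[[pair[2]]]))
    pooled <- structure(list(
      compared = sum(vapply(per_gene, function(z) z$compared, integer(1))),
      transitions = sum(vapply(per_gene, function(z) z$transitions, integer(1))),
      transversions = sum(vapply(per_gene, function(z) z$transversions, integer(1))),
      excluded = sum(vapply(per_gene, function(z) z$excluded, integer(1)))
    ), class = "site_comparison")
    expect_equal(unclass(whole), unclass(pooled))
    expect_equal(k2p_distance(whole), k2p_distance(pooled))
  }
})

test_that("distance matrix agrees with per-pair recomputation and the ape oracle", {
  set <- make_gene_set(strains = c("s1", "s2", "s3"), seed = 19)
  m <- mlsa_distance_matrix(set)
  expect_equal(diag(m), c(s1 = 0, s2 = 0, s3 = 0))
  expect_equal(m, t(m))
  cc <- concatenate_mlsa(set)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(m[i, j],
                 k2p_distance(classify_sites(cc[[i]], cc[[j]])))
  }
  # independent implementation: ape's K80 with pairwise deletion
  skip_if_not_installed("ape")
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(cc), "")))
  oracle <- as.matrix(ape::dist.dna(bin, model = "K80",
                                    pairwise.deletion = TRUE))
  expect_equal(unname(m), unname(oracle[rownames(m), colnames(m)]),
               tolerance = 1e-10)
})

test_that("identical strains give a zero matrix", {
  set <- make_gene_set(strains = "s1")
  genes <- lapply(set$genes, function(g) {
    out <- c(g[["s1"]], g[["s1"]])
    names(out) <- c("s1", "s2")
    out
  })
  m <- mlsa_distance_matrix(gene_alignment_set(genes))
  expect_equal(unname(m), matrix(0, 2, 2))
})

test_that("distance matrices survive TSV and PHYLIP serialization", {
  set <- make_gene_set(strains = c("s1", "s2", "s3"), seed = 3)
  m <- mlsa_distance_matrix(set)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(m, tsv)
  back <- read_distance_matrix(tsv)
  expect_equal(back, m, tolerance = 1e-4)  # values printed to 6 dp

  phy <- withr::local_tempfile(fileext = ".phy")
  write_distance_matrix(m, phy, format = "phylip")
  lines <- readLines(phy)
  expect_equal(length(lines), nrow(m) + 1L)
  expect_equal(as.integer(trimws(lines[1])), nrow(m))
})

test_that("FASTA loading round-trips an alignment set", {
  set <- make_gene_set(strains = c("X1", "X2"), seed = 5)
  paths <- write_gene_fastas(set)
  loaded <- load_gene_fastas(paths)
  expect_equal(loaded$genes, set$genes)
  # descriptions after whitespace are stripped from record ids
  p2 <- paths
  alt <- withr::local_tempfile(fileext = ".fasta")
  seqs <- set$genes$atpD
  writeLines(paste0(">", names(seqs), " some description\n", seqs), alt)
  p2[["atpD"]] <- alt
  expect_equal(load_gene_fastas(p2)$genes$atpD, set$genes$atpD)
  expect_error(load_gene_fastas(paths[1:3]), "five genes")
})
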