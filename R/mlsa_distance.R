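#' Canonical MLSA gene order
#'
#' The five housekeeping genes of the *Streptomyces* MLSA scheme, in the
#' fixed order in which per-gene alignments are concatenated head-to-tail.
#' @export
MLSA_GENES <- c("atpD", "gyrB", "recA", "rpoB", "trpB")

#' Build a validated per-gene alignment set
#'
#' Holds one pre-aligned, pre-trimmed, in-frame nucleotide alignment per
#' housekeeping gene, keyed by strain id. No alignment or trimming is
#' performed here: inputs must arrive aligned, and the constructor only
#' validates. Three invariants are enforced per gene: all sequences have
#' identical length; the aligned length is a multiple of 3 (the in-frame
#' rule); and every strain present in one gene is present in all five.
#'
#' @param genes named list, one entry per gene in [MLSA_GENES] (any order),
#'   each a named character vector of aligned sequences keyed by strain id.
#' @return An object of class `gene_alignment_set` with the genes stored in
#'   canonical order.
#' @export
gene_alignment_set <- function(genes) {
  if (!setequal(names(genes), MLSA_GENES))
    stop("need exactly the five genes ", paste(MLSA_GENES, collapse = ", "),
         "; got: ", paste(names(genes), collapse = ", "), call. = FALSE)
  genes <- genes[MLSA_GENES]
  for (g in MLSA_GENES) {
    seqs <- genes[[g]]
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("gene ", g, ": sequences must be named by strain id",
           call. = FALSE)
    len <- nchar(seqs)
    if (length(unique(len)) != 1L) {
      off <- names(seqs)[len != len[1L]]
      stop(sprintf(
        "alignment error in gene %s: unequal sequence lengths (e.g. %s)",
        g, paste(utils::head(off, 3L), collapse = ", ")), call. = FALSE)
    }
    if (len[1L] %% 3L != 0L)
      stop(sprintf("frame error in gene %s: aligned length %d is not a multiple of 3",
                   g, len[1L]), call. = FALSE)
  }
  strains <- sort(names(genes[[1L]]))
  for (g in MLSA_GENES[-1L]) {
    if (!identical(sort(names(genes[[g]])), strains)) {
      diff <- union(setdiff(strains, names(genes[[g]])),
                    setdiff(names(genes[[g]]), strains))
      stop(sprintf("membership error: strain(s) %s not present in all genes (gene %s differs)",
                   paste(diff, collapse = ", "), g), call. = FALSE)
    }
  }
  structure(list(genes = genes, strains = names(genes[[1L]])),
            class = "gene_alignment_set")
}

#' Load the five per-gene FASTA alignments
#'
#' Reads one aligned FASTA file per gene; record ids (first whitespace
#' token of each header) are the strain ids. Validation is delegated to
#' [gene_alignment_set()].
#'
#' @param paths named character vector of file paths; names must be exactly
#'   `atpD, gyrB, recA, rpoB, trpB` (any order).
#' @return A `gene_alignment_set`.
#' @export
load_gene_fastas <- function(paths) {
  if (!setequal(names(paths), MLSA_GENES))
    stop("paths must be named by the five genes ",
         paste(MLSA_GENES, collapse = ", "), call. = FALSE)
  genes <- lapply(paths[MLSA_GENES], function(p) {
    if (!file.exists(p)) stop("no such FASTA file: ", p, call. = FALSE)
    x <- Biostrings::readDNAStringSet(p)
    seqs <- as.character(x)
    names(seqs) <- sub("\\s.*$", "", names(x))
    seqs
  })
  gene_alignment_set(genes)
}

#' Concatenate the five gene alignments for one or all strains
#'
#' Joins the per-gene sequences head-to-tail in the canonical
#' atpD-gyrB-recA-rpoB-trpB order, so the concatenated length is the sum of
#' the five aligned gene lengths and the in-frame property is preserved.
#'
#' @param set a `gene_alignment_set`.
#' @param strain a single strain id, or `NULL` for all strains.
#' @return A named character vector of concatenated sequences.
#' @export
concatenate_mlsa <- function(set, strain = NULL) {
  stopifnot(inherits(set, "gene_alignment_set"))
  strains <- if (is.null(strain)) set$strains else strain
  unknown <- setdiff(strains, set$strains)
  if (length(unknown) > 0L)
    stop("unknown strain(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- vapply(strains, function(s) {
    paste(vapply(set$genes, function(g) g[[s]], character(1L)),
          collapse = "")
  }, character(1L))
  names(out) <- strains
  out
}

# Site classification alphabet: only unambiguous A/C/G/T count as compared
# sites; U is read as T; gaps and every other IUPAC symbol exclude the site
# in both sequences (pairwise deletion, the MEGA-style K2P default).
.TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

#' Classify aligned sites of a sequence pair
#'
#' Walks two equal-length aligned sequences and counts, under pairwise
#' deletion, the sites compared (both bases unambiguous A/C/G/T), the
#' transitions (A<->G, C<->T), the transversions (any other mismatch of
#' unambiguous bases), and the excluded sites (gap or ambiguity code in
#' either sequence). `compared + excluded` equals the alignment length.
#'
#' @param seq_a,seq_b equal-length nucleotide strings (case-insensitive;
#'   U is treated as T).
#' @return An object of class `site_comparison`: a list with elements
#'   `compared`, `transitions`, `transversions`, `excluded`.
#' @export
classify_sites <- function(seq_a, seq_b) {
  a <- chartr("U", "T", toupper(seq_a))
  b <- chartr("U", "T", toupper(seq_b))
  if (nchar(a) != nchar(b))
    stop(sprintf("sequence lengths differ: %d vs %d", nchar(a), nchar(b)),
         call. = FALSE)
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  valid <- ca %in% names(.TS_PARTNER) & cb %in% names(.TS_PARTNER)
  mismatch <- valid & ca != cb
  ts <- mismatch & !is.na(.TS_PARTNER[ca]) & .TS_PARTNER[ca] == cb
  ts[is.na(ts)] <- FALSE
  structure(list(
    compared = sum(valid),
    transitions = sum(ts),
    transversions = sum(mismatch) - sum(ts),
    excluded = sum(!valid)
  ), class = "site_comparison")
}

#' Kimura two-parameter distance from site-change proportions
#'
#' The closed form `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`, where `P`
#' and `Q` are the proportions of compared sites showing a transition and a
#' transversion, respectively. Defined only while both logarithm factors
#' are positive; beyond that the sequences are saturated and the distance
#' is not estimable.
#'
#' @param p,q transition and transversion proportions.
#' @return Distance in substitutions per site.
#' @export
k2p_from_proportions <- function(p, q) {
  stopifnot(p >= 0, q >= 0)
  w1 <- 1 - 2 * p - q
  w2 <- 1 - 2 * q
  if (w1 <= 0 || w2 <= 0)
    stop(sprintf(
      "saturation: K2P distance undefined for P=%.4g, Q=%.4g (log argument <= 0)",
      p, q), call. = FALSE)
  -0.5 * log(w1 * sqrt(w2))
}

#' Kimura two-parameter distance of a classified sequence pair
#'
#' @param comparison a `site_comparison` from [classify_sites()], or a pair
#'   of sequences may be classified first by the caller.
#' @return Distance in substitutions per site; 0 exactly when the compared
#'   sites show no mismatch.
#' @export
k2p_distance <- function(comparison) {
  stopifnot(inherits(comparison, "site_comparison"))
  if (comparison$compared == 0L)
    stop("no overlapping unambiguous sites: distance undefined",
         call. = FALSE)
  k2p_from_proportions(comparison$transitions / comparison$compared,
                       comparison$transversions / comparison$compared)
}

#' Pairwise MLSA distance matrix
#'
#' Concatenates the five-gene alignment for every strain and computes all
#' pairwise K2P distances. The result is symmetric with a zero diagonal. A
#' saturated pair (K2P log argument non-positive) is flagged as `NA` in its
#' cell and reported in a warning rather than silently dropped; with the
#' working range of *Streptomyces* MLSA distances (<= 0.05) saturation
#' indicates malformed input.
#'
#' @param set a `gene_alignment_set` with at least two strains.
#' @return A square numeric matrix with strain ids as dimnames.
#' @export
mlsa_distance_matrix <- function(set) {
  stopifnot(inherits(set, "gene_alignment_set"))
  strains <- set$strains
  if (length(strains) < 2L)
    stop("need at least two strains for a distance matrix", call. = FALSE)
  seqs <- concatenate_mlsa(set)
  n <- length(strains)
  m <- matrix(0, n, n, dimnames = list(strains, strains))
  saturated <- character(0L)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- tryCatch(
        k2p_distance(classify_sites(seqs[[i]], seqs[[j]])),
        error = function(e) {
          saturated <<- c(saturated,
                          paste(strains[i], strains[j], sep = " / "))
          NA_real_
        })
      m[i, j] <- m[j, i] <- d
    }
  }
  if (length(saturated) > 0L)
    warning("distance undefined (saturation or no overlap) for pair(s): ",
            paste(saturated, collapse = "; "), call. = FALSE)
  m
}

#' Write / read a distance matrix
#'
#' `write_distance_matrix()` emits either a square TSV (strain ids in the
#' first row and column, 6 decimal places) or a lower-triangle
#' PHYLIP-style file; `read_distance_matrix()` reads the TSV form back.
#'
#' @param m square distance matrix with dimnames.
#' @param path file path.
#' @param format `"tsv"` or `"phylip"`.
#' @return `path` invisibly; for the reader, the matrix.
#' @export
write_distance_matrix <- function(m, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  ids <- rownames(m)
  if (format == "tsv") {
    lines <- c(paste(c("", ids), collapse = "\t"),
               vapply(seq_along(ids), function(i) {
                 paste(c(ids[i], sprintf("%.6f", m[i, ])), collapse = "\t")
               }, character(1L)))
  } else {
    lines <- c(sprintf("%5d", nrow(m)),
               vapply(seq_along(ids), function(i) {
                 row <- if (i == 1L) character(0L)
                        else sprintf("%.6f", m[i, seq_len(i - 1L)])
                 paste(c(sprintf("%-10s", ids[i]), row), collapse = "  ")
               }, character(1L)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE)
  as.matrix(df)
}
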