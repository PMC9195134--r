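METRIC_COLUMNS <- c("species_a", "species_b", "anim", "mlsa", "ddh")

#' Construct a validated strain-pair metric table
#'
#' A metric table holds one row per unordered pair of *Streptomyces* type
#' strains, with the three genome-relatedness metrics used for species
#' delineation: ANIm (average nucleotide identity, MUMmer variant, percent),
#' the MLSA evolutionary distance on the concatenated five-gene alignment
#' (substitutions per site), and dDDH (digital DNA-DNA hybridization,
#' percent).
#'
#' Invariants enforced: `anim` and `ddh` lie in \[0, 100\], `mlsa >= 0`, the
#' two strain labels of a pair differ, and no unordered pair occurs twice
#' (\{A, B\} and \{B, A\} count as the same pair).
#'
#' @param species_a,species_b character vectors of strain labels, stored
#'   verbatim.
#' @param anim,mlsa,ddh numeric metric vectors.
#' @param source provenance label attached to the table.
#' @return A data frame of class `pair_metric_table`.
#' @export
metric_table <- function(species_a, species_b, anim, mlsa, ddh,
                         source = "user") {
  df <- data.frame(
    species_a = as.character(species_a),
    species_b = as.character(species_b),
    anim = as.numeric(anim),
    mlsa = as.numeric(mlsa),
    ddh = as.numeric(ddh),
    stringsAsFactors = FALSE
  )
  validate_metric_table(df)
  structure(df, source = source,
            class = c("pair_metric_table", "data.frame"))
}

validate_metric_table <- function(df) {
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i) > 0L)
      stop(sprintf("invalid metric table: %s (row%s %s)", what,
                   if (length(i) > 1L) "s" else "",
                   paste(i, collapse = ", ")), call. = FALSE)
  }
  bad(!is.finite(df$anim) | df$anim < 0 | df$anim > 100,
      "anim must be a percentage in [0, 100]")
  bad(!is.finite(df$ddh) | df$ddh < 0 | df$ddh > 100,
      "ddh must be a percentage in [0, 100]")
  bad(!is.finite(df$mlsa) | df$mlsa < 0, "mlsa must be >= 0")
  bad(df$species_a == df$species_b, "species_a and species_b must differ")
  key <- paste(pmin(df$species_a, df$species_b),
               pmax(df$species_a, df$species_b), sep = "\r")
  bad(duplicated(key), "duplicated unordered species pair")
  invisible(df)
}

#' The packaged 80-pair Streptomyces metric table
#'
#' Returns the table of 80 type-strain pairs (ANIm, MLSA distance, dDDH)
#' that the threshold analysis is calibrated on, in its printed order. All
#' pairs were pre-filtered to ANIm >= 90%, the range in which ANIm is
#' considered reliable; the loader asserts this together with the usual
#' table invariants and fails hard if the packaged file is missing or
#' corrupted.
#'
#' The first record is the pair *S. flavovariabilis* NRRL B-16367 /
#' *S. variegatus* NRRL B-16380 (ANIm 99.99, MLSA 0.000, dDDH 99.8).
#'
#' @return A `pair_metric_table` with 80 rows.
#' @examples
#' tbl <- streptomyces_pairs()
#' nrow(tbl)
#' @export
streptomyces_pairs <- function() {
  path <- system.file("extdata", "table1_pair_metrics.tsv",
                      package = "strepdelim")
  if (path == "" || !file.exists(path))
    stop("packaged strain-pair table is missing; broken installation",
         call. = FALSE)
  tbl <- read_metric_table(path, delim = "\t")
  if (any(tbl$anim < 90))
    stop("packaged strain-pair table is corrupted: ANIm < 90% found",
         call. = FALSE)
  attr(tbl, "source") <- "packaged"
  tbl
}

#' Read a strain-pair metric table from TSV/CSV
#'
#' The file must carry a header naming the five columns `species_a`,
#' `species_b`, `anim`, `mlsa`, `ddh` (extra columns are ignored). The
#' delimiter is auto-detected from the header line (tab vs comma) unless
#' given.
#'
#' @param path file path.
#' @param delim `"\t"`, `","`, or `NULL` to auto-detect.
#' @return A `pair_metric_table`.
#' @export
read_metric_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(delim)) {
    header <- readLines(path, n = 1L, warn = FALSE)
    delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           fileEncoding = "UTF-8")
  missing <- setdiff(METRIC_COLUMNS, names(raw))
  if (length(missing) > 0L)
    stop("schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0L)
      stop(sprintf("parse error: non-numeric %s at row %d (%s)",
                   col, bad[1L], raw[[col]][bad[1L]]), call. = FALSE)
    v
  }
  metric_table(raw$species_a, raw$species_b,
               num("anim"), num("mlsa"), num("ddh"),
               source = path)
}

#' Write a metric table as TSV
#'
#' Fixed column order (`species_a`, `species_b`, `anim`, `mlsa`, `ddh`) and
#' fixed numeric formatting at the precision the metrics are reported at:
#' 2 decimals for ANIm, 3 for the MLSA distance, 1 for dDDH. A table
#' written and read back compares equal.
#'
#' @param table a `pair_metric_table`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(table, path) {
  out <- data.frame(
    species_a = table$species_a,
    species_b = table$species_b,
    anim = sprintf("%.2f", table$anim),
    mlsa = sprintf("%.3f", table$mlsa),
    ddh = sprintf("%.1f", table$ddh),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) {
    stop(sprintf("failed to write %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(path)
}

# Parse an interval constraint. Accepts:
#   a length-2 numeric c(lo, hi)          -> closed on both ends
#   ">=x", ">x", "<=x", "<x"              -> one-sided
#   "[lo,hi]", "[lo,hi)", "(lo,hi]", "(lo,hi)" -> explicit bounds
# Absent bounds are unbounded. Returns list(lo, hi, lo_open, hi_open).
parse_interval <- function(spec, name = "interval") {
  fail <- function() stop(sprintf("cannot parse %s spec: %s", name,
                                  deparse(spec)), call. = FALSE)
  if (is.numeric(spec)) {
    if (length(spec) != 2L) fail()
    iv <- list(lo = spec[1L], hi = spec[2L],
               lo_open = FALSE, hi_open = FALSE)
  } else if (is.character(spec) && length(spec) == 1L) {
    s <- gsub("[[:space:]]", "", spec)
    if (grepl("^[\\[(].+,.+[])]$", s)) {
      lo_open <- substr(s, 1L, 1L) == "("
      hi_open <- substr(s, nchar(s), nchar(s)) == ")"
      body <- strsplit(substr(s, 2L, nchar(s) - 1L), ",", fixed = TRUE)[[1L]]
      if (length(body) != 2L) fail()
      iv <- list(lo = as.numeric(body[1L]), hi = as.numeric(body[2L]),
                 lo_open = lo_open, hi_open = hi_open)
    } else if (grepl("^(>=|>|<=|<)", s)) {
      op <- regmatches(s, regexpr("^(>=|>|<=|<)", s))
      val <- as.numeric(sub("^(>=|>|<=|<)", "", s))
      iv <- switch(op,
        ">=" = list(lo = val, hi = Inf, lo_open = FALSE, hi_open = FALSE),
        ">"  = list(lo = val, hi = Inf, lo_open = TRUE,  hi_open = FALSE),
        "<=" = list(lo = -Inf, hi = val, lo_open = FALSE, hi_open = FALSE),
        "<"  = list(lo = -Inf, hi = val, lo_open = FALSE, hi_open = TRUE))
    } else fail()
  } else fail()
  if (is.na(iv$lo) || is.na(iv$hi)) fail()
  if (iv$lo > iv$hi)
    stop(sprintf("inverted %s: lower bound %g > upper bound %g",
                 name, iv$lo, iv$hi), call. = FALSE)
  iv
}

in_interval <- function(x, iv) {
  lo_ok <- if (iv$lo_open) x > iv$lo else x >= iv$lo
  hi_ok <- if (iv$hi_open) x < iv$hi else x <= iv$hi
  lo_ok & hi_ok
}

#' Filter or count strain pairs by metric intervals
#'
#' Selects the records satisfying all supplied constraints. Each constraint
#' is an interval over one metric, given either as a comparison string
#' (`">=0.008"`, `"<70"`) or in bracket notation with explicit open/closed
#' ends (`"[0.008,0.014)"`); a length-2 numeric vector means a closed
#' interval. Omitted metrics are unconstrained. Bracket notation matters
#' here because the delineation rule's middle tier is the half-open band
#' \[0.008, 0.014).
#'
#' @param table a `pair_metric_table`.
#' @param mlsa,ddh,anim optional interval constraints.
#' @return `filter_pairs()` returns the subsetted `pair_metric_table`;
#'   `count_pairs()` the number of matching records.
#' @examples
#' tbl <- streptomyces_pairs()
#' count_pairs(tbl, mlsa = ">=0.008", ddh = ">70")   # deviating pairs
#' count_pairs(tbl, mlsa = "[0.008,0.014)", ddh = "<70")
#' @export
filter_pairs <- function(table, mlsa = NULL, ddh = NULL, anim = NULL) {
  keep <- rep(TRUE, nrow(table))
  if (!is.null(mlsa))
    keep <- keep & in_interval(table$mlsa, parse_interval(mlsa, "mlsa"))
  if (!is.null(ddh))
    keep <- keep & in_interval(table$ddh, parse_interval(ddh, "ddh"))
  if (!is.null(anim))
    keep <- keep & in_interval(table$anim, parse_interval(anim, "anim"))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, source = attr(table, "source"),
            class = c("pair_metric_table", "data.frame"))
}

#' @rdname filter_pairs
#' @export
count_pairs <- function(table, mlsa = NULL, ddh = NULL, anim = NULL) {
  nrow(filter_pairs(table, mlsa = mlsa, ddh = ddh, anim = anim))
}
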