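#' The six verdict states of the delineation rule
#' @export
VERDICT_STATES <- c("CONSPECIFIC_MLSA", "DISTINCT_MLSA",
                    "GENOME_METRICS_REQUIRED",
                    "CONSPECIFIC_GENOME", "DISTINCT_GENOME",
                    "BORDERLINE_POLYPHASIC")

#' Thresholds of the three-tier delineation rule
#'
#' The rule's tunable constants. The MLSA tiers are `mlsa_low = 0.008`
#' (below: same genomic species) and `mlsa_high = 0.014` (at or above:
#' distinct species); the half-open band in between requires a genome
#' metric. The genome-metric cuts are the classical 70% dDDH boundary and
#' its ANIm equivalent 96.7% obtained from the cross-metric regression.
#' `ddh_band` and `ani_band` set how far below a cut a value still counts
#' as "close to" it, i.e. dDDH in \[68, 70) or ANIm in \[95.7, 96.7) defer
#' to polyphasic evidence instead of declaring distinct species; the widths
#' are a documented reconstruction (they select exactly the five packaged
#' pairs that needed polyphasic reevaluation) and are configurable.
#'
#' @param mlsa_low,mlsa_high MLSA distance tier bounds (substitutions/site),
#'   `0 < mlsa_low < mlsa_high`.
#' @param ddh_cut,ani_cut genome-metric cut-offs in percent, within (0,100).
#' @param ddh_band,ani_band borderline band widths in percentage points,
#'   `> 0`.
#' @return An object of class `delineation_thresholds`.
#' @export
delineation_thresholds <- function(mlsa_low = 0.008, mlsa_high = 0.014,
                                   ddh_cut = 70, ani_cut = 96.7,
                                   ddh_band = 2.0, ani_band = 1.0) {
  stopifnot(mlsa_low > 0, mlsa_low < mlsa_high,
            ddh_band > 0, ani_band > 0,
            ddh_cut > 0, ddh_cut < 100, ani_cut > 0, ani_cut < 100)
  structure(list(mlsa_low = mlsa_low, mlsa_high = mlsa_high,
                 ddh_cut = ddh_cut, ani_cut = ani_cut,
                 ddh_band = ddh_band, ani_band = ani_band),
            class = "delineation_thresholds")
}

#' Classify one strain pair
#'
#' Applies the three-tier decision rule. When a genome metric (dDDH or
#' ANIm) is supplied it decides the verdict regardless of the MLSA tier —
#' either metric reaching its cut is sufficient for conspecificity; a value
#' below both cuts but inside a borderline band defers to polyphasic
#' evidence (`BORDERLINE_POLYPHASIC`); otherwise the pair is a distinct
#' species. With only the MLSA distance available, `mlsa < mlsa_low` means
#' the strains are heterotypic synonyms (`CONSPECIFIC_MLSA`),
#' `mlsa >= mlsa_high` a new species (`DISTINCT_MLSA`), and the band in
#' between requires computing a genome metric
#' (`GENOME_METRICS_REQUIRED`). The returned rationale records the fired
#' rule, including any conflict where one genome metric clears its cut
#' while the other falls below cut minus band.
#'
#' @param mlsa MLSA distance (substitutions/site) or `NULL`.
#' @param ddh dDDH percentage or `NULL`.
#' @param anim ANIm percentage or `NULL`.
#' @param thresholds a [delineation_thresholds()] object.
#' @return An object of class `verdict`: list with `state` (one of
#'   [VERDICT_STATES]) and `rationale`.
#' @examples
#' classify_pair(mlsa = 0.005)$state
#' classify_pair(mlsa = 0.010, ddh = 72.0, anim = 96.90)$state
#' classify_pair(ddh = 69.5, anim = 96.69)$state
#' @export
classify_pair <- function(mlsa = NULL, ddh = NULL, anim = NULL,
                          thresholds = delineation_thresholds()) {
  t <- thresholds
  stopifnot(inherits(t, "delineation_thresholds"))
  if (is.null(mlsa) && is.null(ddh) && is.null(anim))
    stop("at least one metric must be provided", call. = FALSE)
  chk <- function(v, name, lo, hi) {
    if (!is.null(v) && (!is.finite(v) || v < lo || v > hi))
      stop(sprintf("%s = %s outside [%g, %g]", name, format(v), lo, hi),
           call. = FALSE)
  }
  chk(mlsa, "mlsa", 0, Inf)
  chk(ddh, "ddh", 0, 100)
  chk(anim, "anim", 0, 100)

  verdict <- function(state, rationale)
    structure(list(state = state, rationale = rationale), class = "verdict")

  if (!is.null(ddh) || !is.null(anim)) {
    ddh_ok <- !is.null(ddh) && ddh >= t$ddh_cut
    ani_ok <- !is.null(anim) && anim >= t$ani_cut
    if (ddh_ok || ani_ok) {
      why <- c(
        if (ddh_ok) sprintf("dDDH %.1f >= %.1f", ddh, t$ddh_cut),
        if (ani_ok) sprintf("ANIm %.2f >= %.2f", anim, t$ani_cut))
      conflict <- c(
        if (!is.null(ddh) && !ddh_ok && ddh < t$ddh_cut - t$ddh_band)
          sprintf("conflict: dDDH %.1f < %.1f", ddh, t$ddh_cut - t$ddh_band),
        if (!is.null(anim) && !ani_ok && anim < t$ani_cut - t$ani_band)
          sprintf("conflict: ANIm %.2f < %.2f", anim, t$ani_cut - t$ani_band))
      return(verdict("CONSPECIFIC_GENOME",
                     paste(c(why, conflict), collapse = "; ")))
    }
    ddh_border <- !is.null(ddh) && ddh >= t$ddh_cut - t$ddh_band
    ani_border <- !is.null(anim) && anim >= t$ani_cut - t$ani_band
    if (ddh_border || ani_border) {
      why <- c(
        if (ddh_border) sprintf("dDDH %.1f in [%.1f, %.1f)",
                                ddh, t$ddh_cut - t$ddh_band, t$ddh_cut),
        if (ani_border) sprintf("ANIm %.2f in [%.2f, %.2f)",
                                anim, t$ani_cut - t$ani_band, t$ani_cut))
      return(verdict("BORDERLINE_POLYPHASIC",
                     paste(c(why,
                             "polyphasic evidence required (phenotype, chemotaxonomy, phylogenomics)"),
                           collapse = "; ")))
    }
    why <- c(
      if (!is.null(ddh)) sprintf("dDDH %.1f < %.1f",
                                 ddh, t$ddh_cut - t$ddh_band),
      if (!is.null(anim)) sprintf("ANIm %.2f < %.2f",
                                  anim, t$ani_cut - t$ani_band))
    return(verdict("DISTINCT_GENOME", paste(why, collapse = "; ")))
  }

  if (mlsa < t$mlsa_low)
    return(verdict("CONSPECIFIC_MLSA",
                   sprintf("MLSA %.3f < %.3f: heterotypic synonym",
                           mlsa, t$mlsa_low)))
  if (mlsa >= t$mlsa_high)
    return(verdict("DISTINCT_MLSA",
                   sprintf("MLSA %.3f >= %.3f: new species",
                           mlsa, t$mlsa_high)))
  verdict("GENOME_METRICS_REQUIRED",
          sprintf("MLSA %.3f in [%.3f, %.3f): dDDH or ANIm must be calculated",
                  mlsa, t$mlsa_low, t$mlsa_high))
}

#' @export
print.verdict <- function(x, ...) {
  cat(x$state, "\n  ", x$rationale, "\n", sep = "")
  invisible(x)
}

#' Classify every pair of a metric table
#'
#' Applies [classify_pair()] to each record using all three metrics. Errors
#' on individual records are collected, not fatal: the affected rows get an
#' `NA` state and the error message as rationale.
#'
#' @param table a `pair_metric_table`.
#' @param thresholds a [delineation_thresholds()] object.
#' @return An object of class `delineation_result`: list with `verdicts`
#'   (data frame: species_a, species_b, state, rationale) and `summary`
#'   (named integer counts over [VERDICT_STATES]).
#' @examples
#' res <- classify_table(streptomyces_pairs())
#' res$summary
#' @export
classify_table <- function(table, thresholds = delineation_thresholds()) {
  if (nrow(table) == 0L) stop("empty metric table", call. = FALSE)
  states <- character(nrow(table))
  rationales <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    v <- tryCatch(
      classify_pair(mlsa = table$mlsa[i], ddh = table$ddh[i],
                    anim = table$anim[i], thresholds = thresholds),
      error = function(e) list(state = NA_character_,
                               rationale = conditionMessage(e)))
    states[i] <- v$state
    rationales[i] <- v$rationale
  }
  verdicts <- data.frame(species_a = table$species_a,
                         species_b = table$species_b,
                         state = states, rationale = rationales,
                         stringsAsFactors = FALSE)
  summary <- vapply(VERDICT_STATES, function(s) sum(states == s, na.rm = TRUE),
                    integer(1L))
  structure(list(verdicts = verdicts, summary = summary,
                 n_failed = sum(is.na(states))),
            class = "delineation_result")
}

#' @export
print.delineation_result <- function(x, ...) {
  cat("Delineation of", nrow(x$verdicts), "strain pairs\n")
  for (s in names(x$summary))
    if (x$summary[[s]] > 0L) cat(sprintf("  %-24s %d\n", s, x$summary[[s]]))
  if (x$n_failed > 0L) cat("  records failing validation:", x$n_failed, "\n")
  invisible(x)
}

#' Render verdicts as a text or JSON report
#'
#' @param verdicts a `delineation_result`, or a list of `verdict` objects.
#' @param format `"text"` or `"json"`.
#' @return A character scalar (the report document).
#' @export
verdict_report <- function(verdicts, format = c("text", "json")) {
  format <- match.arg(format)
  if (inherits(verdicts, "delineation_result")) {
    df <- verdicts$verdicts
    summary <- verdicts$summary
  } else {
    if (inherits(verdicts, "verdict")) verdicts <- list(verdicts)
    n <- length(verdicts)
    df <- data.frame(
      species_a = rep(NA_character_, n), species_b = rep(NA_character_, n),
      state = vapply(verdicts, `[[`, character(1L), "state"),
      rationale = vapply(verdicts, `[[`, character(1L), "rationale"),
      stringsAsFactors = FALSE)
    summary <- vapply(VERDICT_STATES,
                      function(s) sum(df$state == s, na.rm = TRUE),
                      integer(1L))
  }
  if (format == "json") {
    return(as.character(jsonlite::toJSON(
      list(verdicts = df, summary = as.list(summary)),
      auto_unbox = TRUE, pretty = TRUE, na = "null")))
  }
  lines <- character(0L)
  if (nrow(df) > 0L) {
    label <- ifelse(is.na(df$species_a), "",
                    paste0(df$species_a, " vs ", df$species_b, ": "))
    lines <- sprintf("%d. %s%s\n   %s", seq_len(nrow(df)), label,
                     df$state, df$rationale)
  }
  lines <- c(lines, "", "Summary:",
             sprintf("  %-24s %d", names(summary), summary))
  paste(lines, collapse = "\n")
}
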