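#' Length-normalized read counts (reads per kilobase)
#'
#' The abundance unit used for desk-scale mito-transcriptome comparisons:
#' raw read count divided by feature length in kb.
#'
#' @param counts Named integer vector (or `feature_counts` data.frame from
#'   [count_by_category()]) of reads per feature.
#' @param lengths_nt Named integer vector of feature lengths in
#'   nucleotides (> 0), covering every counted feature.
#' @return A `data.frame` with `feature_id`, `reads`, `length_kb`,
#'   `reads_per_kb`.
#' @export
reads_per_kb <- function(counts, lengths_nt) {
  if (is.data.frame(counts)) {
    cv <- counts$reads
    names(cv) <- counts$feature_id
    counts <- cv
  }
  ids <- names(lengths_nt)
  if (is.null(ids)) stop("lengths_nt must be named by feature id")
  if (any(lengths_nt <= 0)) stop("feature lengths must be > 0")
  reads <- counts[ids]
  reads[is.na(reads)] <- 0
  data.frame(feature_id = ids, reads = as.integer(reads),
             length_kb = lengths_nt / 1000,
             reads_per_kb = as.numeric(reads) / (lengths_nt / 1000),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Splicing efficiency from junction-spanning read counts
#'
#' Each spliced transcript presents one countable junction (the ligated
#' exons), while each unspliced precursor presents two (the 5'SS and 3'SS
#' flanks); the default summary therefore averages the two flank counts.
#' Because the arithmetic behind published "fraction unspliced" figures is
#' rarely printed, the alternative "sum" summary is also offered; the two
#' agree exactly when the flank counts are equal.
#'
#' @param n_spliced Exon-ligation (E1E2) junction read count.
#' @param n_unspliced_5ss,n_unspliced_3ss Reads flanking the 5' and 3'
#'   splice sites of the unspliced precursor.
#' @param unspliced_formula "mean" (default) or "sum".
#' @param conf_level Confidence level for the Wilson score interval
#'   (computed on the implied integer counts via
#'   [stats::prop.test()] without continuity correction; Wilson rather
#'   than Wald because the counts are small).
#' @return A one-row `data.frame`: `n_spliced`, `n_unspliced_5ss`,
#'   `n_unspliced_3ss`, `unspliced_summary`, `spliced_fraction`,
#'   `unspliced_fraction`, `ci_lower`, `ci_upper`, `formula`.
#' @export
splicing_efficiency <- function(n_spliced, n_unspliced_5ss,
                                n_unspliced_3ss,
                                unspliced_formula = c("mean", "sum"),
                                conf_level = 0.95) {
  unspliced_formula <- match.arg(unspliced_formula)
  stopifnot(n_spliced >= 0, n_unspliced_5ss >= 0, n_unspliced_3ss >= 0)
  u <- switch(unspliced_formula,
              mean = (n_unspliced_5ss + n_unspliced_3ss) / 2,
              sum = n_unspliced_5ss + n_unspliced_3ss)
  if (n_spliced + u < 1)
    return(data.frame(n_spliced = n_spliced,
                      n_unspliced_5ss = n_unspliced_5ss,
                      n_unspliced_3ss = n_unspliced_3ss,
                      unspliced_summary = u, spliced_fraction = NA_real_,
                      unspliced_fraction = NA_real_, ci_lower = NA_real_,
                      ci_upper = NA_real_, formula = unspliced_formula,
                      stringsAsFactors = FALSE))
  frac <- n_spliced / (n_spliced + u)
  x <- round(n_spliced)
  n <- round(n_spliced + u)
  x <- min(x, n)
  ci <- stats::prop.test(x, n, correct = FALSE,
                         conf.level = conf_level)$conf.int
  data.frame(n_spliced = n_spliced, n_unspliced_5ss = n_unspliced_5ss,
             n_unspliced_3ss = n_unspliced_3ss, unspliced_summary = u,
             spliced_fraction = frac, unspliced_fraction = 1 - frac,
             ci_lower = ci[1L], ci_upper = ci[2L],
             formula = unspliced_formula, stringsAsFactors = FALSE)
}

#' Compare spliced-read abundance between two introns
#'
#' Ratio of exon-ligation read counts with a normal-approximation interval
#' on the log ratio (Poisson counts: var(log n) ~ 1/n).
#'
#' @param n_spliced_a,n_spliced_b E1E2 read counts for introns A and B.
#' @param conf_level Confidence level.
#' @return A one-row `data.frame`: `ratio`, `log_ratio`, `ci_lower`,
#'   `ci_upper`, `infinite` (flag set when the denominator is zero).
#' @export
compare_introns <- function(n_spliced_a, n_spliced_b, conf_level = 0.95) {
  if (n_spliced_b == 0)
    return(data.frame(ratio = Inf, log_ratio = Inf, ci_lower = NA_real_,
                      ci_upper = NA_real_, infinite = TRUE,
                      stringsAsFactors = FALSE))
  if (n_spliced_a <= 0) stop("n_spliced_a must be > 0")
  r <- n_spliced_a / n_spliced_b
  se <- sqrt(1 / n_spliced_a + 1 / n_spliced_b)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(ratio = r, log_ratio = log(r),
             ci_lower = exp(log(r) - z * se),
             ci_upper = exp(log(r) + z * se),
             infinite = FALSE, stringsAsFactors = FALSE)
}

#' Build a splicing report from classification counts
#'
#' Collates per-intron junction counts into efficiency estimates (both
#' unspliced summaries side by side), intron-circle and back-splice
#' support tallies, and optional per-feature reads/kb.
#'
#' @param counts A [count_by_category()] object.
#' @param genome Optional [circular_genome()] (needed for reads/kb).
#' @param features Optional [feature_table()] (needed for reads/kb).
#' @param n_backsplice_support Optional named integer vector per intron id
#'   (from [detect_backsplice_support()]).
#' @return An object of class `splicing_report`: list with `introns`
#'   (data.frame, one row per intron and formula), `features` (reads/kb
#'   table or NULL), `counts`.
#' @export
splicing_report <- function(counts, genome = NULL, features = NULL,
                            n_backsplice_support = NULL) {
  stopifnot(inherits(counts, "classification_counts"))
  jc <- counts$junction_counts
  intron_ids <- unique(jc$intron_id)
  get_n <- function(iid, cat) {
    w <- jc$intron_id == iid & jc$category == cat
    if (any(w)) sum(jc$reads[w]) else 0L
  }
  rows <- list()
  for (iid in intron_ids) {
    ns <- get_n(iid, "E1E2_LIGATION")
    n5 <- get_n(iid, "UNSPLICED_5SS")
    n3 <- get_n(iid, "UNSPLICED_3SS")
    ncirc <- get_n(iid, "INTRON_CIRCLE")
    nbs <- if (!is.null(n_backsplice_support) &&
               iid %in% names(n_backsplice_support))
      n_backsplice_support[[iid]] else NA_integer_
    for (f in c("mean", "sum")) {
      eff <- splicing_efficiency(ns, n5, n3, unspliced_formula = f)
      eff$intron_id <- iid
      eff$n_circle <- ncirc
      eff$n_backsplice_support <- nbs
      rows[[length(rows) + 1L]] <- eff
    }
  }
  introns <- if (length(rows)) do.call(rbind, rows) else NULL
  feats <- NULL
  if (!is.null(genome) && !is.null(features) &&
      nrow(counts$feature_counts) > 0L) {
    ln <- feature_length(genome, features)
    names(ln) <- features$id
    feats <- reads_per_kb(counts$feature_counts, ln)
  }
  structure(list(introns = introns, features = feats, counts = counts),
            class = "splicing_report")
}

#' @export
print.splicing_report <- function(x, ...) {
  cat("<splicing_report>\n")
  if (!is.null(x$introns)) {
    cols <- c("intron_id", "formula", "n_spliced", "n_unspliced_5ss",
              "n_unspliced_3ss", "spliced_fraction", "ci_lower", "ci_upper",
              "n_circle")
    df <- x$introns[, cols]
    df$spliced_fraction <- round(df$spliced_fraction, 3)
    df$ci_lower <- round(df$ci_lower, 3)
    df$ci_upper <- round(df$ci_upper, 3)
    print(df, row.names = FALSE)
  } else cat("  (no intron junction counts)\n")
  if (!is.null(x$features)) {
    cat(sprintf("  %d features with reads/kb\n", nrow(x$features)))
  }
  invisible(x)
}

#' Write a splicing report to TSV and JSON
#'
#' @param report A [splicing_report()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_splicing_report <- function(report, dir) {
  stopifnot(inherits(report, "splicing_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (!is.null(report$introns)) {
    p <- file.path(dir, "splicing_efficiency.tsv")
    utils::write.table(report$introns, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(report$features)) {
    p <- file.path(dir, "reads_per_kb.tsv")
    utils::write.table(report$features, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(introns = report$introns, features = report$features,
         totals = list(total = report$counts$total,
                       ambiguous = report$counts$n_ambiguous,
                       unassigned = report$counts$n_unassigned,
                       feature_assigned = report$counts$n_feature_assigned)),
    p, auto_unbox = TRUE, digits = NA, null = "null")
  paths <- c(paths, p)
  invisible(paths)
}
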