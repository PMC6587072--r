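# Curation quality statistics: accuracy, recovery, error profiles,
# throughput and the high- vs low-accuracy effort comparison.

#' Summarise ingested curation rows
#'
#' Unchecked rows never count toward denominators: `n_evaluated` covers
#' only rows a curator actually checked. Percentages are computed at full
#' precision and conventionally reported to one decimal (see
#' `print.curation_report`). The recovery rate is the fraction of
#' evaluated statements that ended up usable — marked correct as-is or
#' successfully corrected — so `recovery_pct = pct_correct + pct_changed`
#' identically.
#'
#' @param rows validated rows from [ingest_sheet()]
#' @return an object of class `curation_report`: counts
#'   (`n_evaluated`, `n_correct`, `n_changed`, `n_uncorrectable`),
#'   percentages (`pct_correct`, `pct_changed`, `pct_uncorrectable`,
#'   `recovery_pct`), `per_gene` (data frame with per-gene accuracy and
#'   recovery percentages), `error_type_counts`, and `undefined` (TRUE when
#'   no rows were evaluated, in which case percentages are `NA`, not NaN)
#' @export
summarize_curation <- function(rows) {
  cls <- classify_rows(rows)
  evaluated <- cls != "unchecked"
  n_evaluated <- sum(evaluated)
  n_correct <- sum(cls == "correct")
  n_changed <- sum(cls == "changed")
  n_uncorrectable <- sum(cls == "uncorrectable")
  undefined <- n_evaluated == 0
  pct <- function(x) if (undefined) NA_real_ else 100 * x / n_evaluated

  per_gene <- NULL
  if (n_evaluated > 0) {
    genes <- rows$gene[evaluated]
    gcls <- cls[evaluated]
    tab <- table(genes)
    gene_names <- names(tab)
    acc <- vapply(gene_names, function(g) {
      100 * sum(gcls == "correct" & genes == g) / sum(genes == g)
    }, numeric(1))
    rec <- vapply(gene_names, function(g) {
      100 * sum(gcls %in% c("correct", "changed") & genes == g) / sum(genes == g)
    }, numeric(1))
    per_gene <- data.frame(
      gene_key = gene_names, n_evaluated = as.integer(tab),
      accuracy_pct = unname(acc), recovery_pct = unname(rec),
      stringsAsFactors = FALSE
    )
    rownames(per_gene) <- NULL
  } else {
    per_gene <- data.frame(
      gene_key = character(0), n_evaluated = integer(0),
      accuracy_pct = numeric(0), recovery_pct = numeric(0),
      stringsAsFactors = FALSE
    )
  }

  err <- rows$error_type[!is.na(rows$error_type)]
  error_type_counts <- if (length(err)) table(err) else table(character(0))

  structure(
    list(
      n_evaluated = n_evaluated,
      n_correct = n_correct,
      n_changed = n_changed,
      n_uncorrectable = n_uncorrectable,
      pct_correct = pct(n_correct),
      pct_changed = pct(n_changed),
      pct_uncorrectable = pct(n_uncorrectable),
      recovery_pct = pct(n_correct + n_changed),
      per_gene = per_gene,
      error_type_counts = error_type_counts,
      undefined = undefined
    ),
    class = "curation_report"
  )
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report\n")
  cat(sprintf("  evaluated:      %d\n", x$n_evaluated))
  if (x$undefined) {
    cat("  no rows evaluated; percentages undefined\n")
    return(invisible(x))
  }
  cat(sprintf("  correct:        %d (%.1f%%)\n", x$n_correct, x$pct_correct))
  cat(sprintf("  changed:        %d (%.1f%%)\n", x$n_changed, x$pct_changed))
  cat(sprintf("  uncorrectable:  %d (%.1f%%)\n", x$n_uncorrectable, x$pct_uncorrectable))
  cat(sprintf("  recovery:       %.1f%%\n", x$recovery_pct))
  if (length(x$error_type_counts)) {
    cat("  error types:\n")
    for (nm in names(sort(x$error_type_counts, decreasing = TRUE))) {
      cat(sprintf("    %-24s %d\n", nm, x$error_type_counts[[nm]]))
    }
  }
  invisible(x)
}

#' Curation throughput in edges per minute
#'
#' @param n_edges number of BEL statements produced
#' @param hours total curation hours (must be positive)
#' @return edges per minute at full precision; conventionally reported to
#'   two decimals
#' @export
throughput <- function(n_edges, hours) {
  if (!is.numeric(hours) || length(hours) != 1 || hours <= 0) {
    stop("hours must be a single positive number")
  }
  n_edges / (hours * 60)
}

#' Error-type profile of curated rows
#'
#' Counts error-type annotations and expresses each as a fraction of the
#' rows needing intervention (changed + uncorrectable). Rows may lack an
#' annotation, so the fractions sum to at most 1.
#'
#' @param rows validated rows from [ingest_sheet()]
#' @return data frame with columns `error_type`, `count`, `fraction`,
#'   sorted by descending count
#' @export
error_profile <- function(rows) {
  cls <- classify_rows(rows)
  denom <- sum(cls %in% c("changed", "uncorrectable"))
  err <- rows$error_type[!is.na(rows$error_type)]
  if (!length(err)) {
    return(data.frame(error_type = character(0), count = integer(0),
                      fraction = numeric(0), stringsAsFactors = FALSE))
  }
  tab <- sort(table(err), decreasing = TRUE)
  data.frame(
    error_type = names(tab),
    count = as.integer(tab),
    fraction = if (denom > 0) as.integer(tab) / denom else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Compare curation effort between high- and low-accuracy genes
#'
#' Selects the top-k and bottom-k genes by per-gene accuracy and compares
#' their curation effort with a two-sample t-test (Welch by default; the
#' classical pooled-variance test is available via `var_equal = TRUE`).
#'
#' @param per_gene_accuracy named numeric vector, accuracy percentage per
#'   gene key
#' @param k group size; the top-k and bottom-k genes are compared
#'   (requires `2 <= k <= n/2`)
#' @param per_gene_effort named numeric vector, curation minutes per gene
#' @param var_equal pooled-variance t-test instead of Welch
#' @return list with `mean_top`, `mean_bottom`, `t`, `p_value`, `df`,
#'   `method`, `top_genes`, `bottom_genes`
#' @export
compare_groups <- function(per_gene_accuracy, k, per_gene_effort,
                           var_equal = FALSE) {
  n <- length(per_gene_accuracy)
  if (k < 2) stop("group size must be at least 2")
  if (k > n / 2) stop("k must not exceed half the number of genes")
  missing_effort <- setdiff(names(per_gene_accuracy), names(per_gene_effort))
  if (length(missing_effort)) {
    stop(sprintf("no effort recorded for gene(s): %s",
                 paste(utils::head(missing_effort, 5), collapse = ", ")))
  }
  ord <- order(per_gene_accuracy, names(per_gene_accuracy),
               decreasing = TRUE, method = "radix")
  top <- names(per_gene_accuracy)[ord][seq_len(k)]
  bottom <- rev(names(per_gene_accuracy)[ord])[seq_len(k)]
  tt <- stats::t.test(per_gene_effort[top], per_gene_effort[bottom],
                      var.equal = var_equal)
  list(
    mean_top = unname(tt$estimate[1]),
    mean_bottom = unname(tt$estimate[2]),
    t = unname(tt$statistic),
    p_value = tt$p.value,
    df = unname(tt$parameter),
    method = tt$method,
    top_genes = top,
    bottom_genes = bottom
  )
}

#' Write a curation report as JSON
#'
#' @param report a `curation_report`
#' @param path output file
#' @return the path, invisibly
#' @export
write_report <- function(report, path) {
  out <- report[c(
    "n_evaluated", "n_correct", "n_changed", "n_uncorrectable",
    "pct_correct", "pct_changed", "pct_uncorrectable", "recovery_pct"
  )]
  out$error_type_counts <- as.list(report$error_type_counts)
  out$per_gene <- report$per_gene
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
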