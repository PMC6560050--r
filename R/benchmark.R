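# Scoring density-functional predictions of dE_elec against CCSD(T)/CBS
# references: signed errors, MSE/MUE/MaxE, volt-threshold accuracy groups,
# and rankings.

.round2 <- function(x) round(x, 2)  # round-half-even at 2 dp, as reported

#' Signed prediction errors per (functional, complex)
#'
#' @param predictions data frame with columns `functional`, `complex_id`,
#'   `delta_e_kcal` (DFT predictions of dE_elec, kcal/mol).
#' @param references data frame with columns `complex_id`, `delta_e_kcal`
#'   (the CCSD(T)/CBS references, kcal/mol).
#' @return A data frame `functional`, `complex_id`, `signed_error`
#'   (prediction - reference, kcal/mol).
#' @export
signed_errors <- function(predictions, references) {
  for (nm in c("functional", "complex_id", "delta_e_kcal")) {
    if (!nm %in% names(predictions)) {
      stop("`predictions` needs column ", nm, call. = FALSE)
    }
  }
  for (nm in c("complex_id", "delta_e_kcal")) {
    if (!nm %in% names(references)) {
      stop("`references` needs column ", nm, call. = FALSE)
    }
  }
  unmatched <- setdiff(predictions$complex_id, references$complex_id)
  if (length(unmatched)) {
    stop("predictions for complexes with no reference value: ",
         paste(unique(unmatched), collapse = ", "), call. = FALSE)
  }
  ref <- stats::setNames(references$delta_e_kcal, references$complex_id)
  data.frame(
    functional = predictions$functional,
    complex_id = predictions$complex_id,
    signed_error = predictions$delta_e_kcal - unname(ref[predictions$complex_id]),
    stringsAsFactors = FALSE
  )
}

.check_errors <- function(errors) {
  if (length(errors) == 0L) stop("no error records", call. = FALSE)
  if (!is.numeric(errors)) stop("errors must be numeric", call. = FALSE)
}

#' Benchmark error statistics
#'
#' Mean signed error, mean unsigned error, and maximum absolute error with
#' the complex where it occurs.  For `maxe()`, ties on the maximum are broken
#' by canonical complex order ([iron_complexes()]), then input order.
#'
#' @param errors numeric vector of signed errors (kcal/mol).
#' @param complex_id optional character vector parallel to `errors`.
#' @return `mse()`/`mue()` a number; `maxe()` a list with `value` (magnitude)
#'   and `complex_id` (or `NA` if no ids were given).
#' @export
mse <- function(errors) { .check_errors(errors); mean(errors) }

#' @rdname mse
#' @export
mue <- function(errors) { .check_errors(errors); mean(abs(errors)) }

#' @rdname mse
#' @export
maxe <- function(errors, complex_id = NULL) {
  .check_errors(errors)
  a <- abs(errors)
  hits <- which(a == max(a))
  if (is.null(complex_id)) {
    return(list(value = max(a), complex_id = NA_character_))
  }
  stopifnot(length(complex_id) == length(errors))
  canon <- iron_complexes()$complex_id
  pos <- match(complex_id[hits], canon)
  pos[is.na(pos)] <- length(canon) + seq_len(sum(is.na(pos)))
  pick <- hits[order(pos)][1]
  list(value = a[pick], complex_id = complex_id[pick])
}

#' Accuracy-group thresholds
#'
#' Functionals are binned by MUE: group I below an error of
#' `potential_step` volts per electron transferred, group II below twice
#' that, group III above.  With the defaults (0.1 V, one electron) the
#' boundaries are 2.3061 and 4.6121 kcal/mol; `strict_paper = TRUE` uses the
#' display-rounded 2.31 and 4.62 instead.
#'
#' @param potential_step group-I boundary in volts per electron.
#' @param electrons electrons transferred (1 for Fe(III)/Fe(II)).
#' @param strict_paper use the 2-dp rounded boundaries.
#' @return A `group_thresholds` list with `group1_max`, `group2_max`
#'   ([quantity()] kcal/mol) and `electrons`.
#' @export
group_thresholds <- function(potential_step = 0.1, electrons = 1L,
                             strict_paper = FALSE) {
  g1 <- volts_to_kcal(quantity(potential_step, "volt"), electrons)
  g2 <- volts_to_kcal(quantity(2 * potential_step, "volt"), electrons)
  if (strict_paper) {
    # the boundaries as printed: 2.31 and its double 4.62
    g1 <- quantity(.round2(qty_value(g1)), "kcal_per_mol")
    g2 <- quantity(2 * qty_value(g1), "kcal_per_mol")
  }
  if (qty_value(g1) >= qty_value(g2)) {
    stop("group1_max must be below group2_max", call. = FALSE)
  }
  structure(list(group1_max = g1, group2_max = g2,
                 electrons = as.integer(electrons)),
            class = "group_thresholds")
}

#' Classify a functional's MUE into accuracy group I, II or III
#'
#' Boundaries are inclusive downward: a MUE equal to a boundary falls in the
#' better group.
#'
#' @param mue_value MUE in kcal/mol (non-negative).
#' @param thresholds a [group_thresholds()].
#' @return `"I"`, `"II"` or `"III"` (vectorised over `mue_value`).
#' @export
classify_group <- function(mue_value, thresholds = group_thresholds()) {
  stopifnot(inherits(thresholds, "group_thresholds"))
  if (any(mue_value < 0)) stop("MUE cannot be negative", call. = FALSE)
  g1 <- qty_value(thresholds$group1_max)
  g2 <- qty_value(thresholds$group2_max)
  ifelse(mue_value <= g1, "I", ifelse(mue_value <= g2, "II", "III"))
}

#' Rank benchmark summaries
#'
#' Ascending by MUE; ties broken by smaller MaxE, then lexicographic
#' functional name.  Assigns `rank` 1..n.
#'
#' @param summaries data frame with columns `functional`, `mue`, `maxe`.
#' @return The same data frame, reordered, with a `rank` column.
#' @export
rank_functionals <- function(summaries) {
  if (nrow(summaries) == 0L) stop("no summaries to rank", call. = FALSE)
  ord <- order(summaries$mue, summaries$maxe, summaries$functional)
  out <- summaries[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

.summarise_errors <- function(errors) {
  split_err <- split(errors, errors$functional)
  rows <- lapply(names(split_err), function(f) {
    e <- split_err[[f]]
    mx <- maxe(e$signed_error, e$complex_id)
    data.frame(functional = f, n = nrow(e),
               mse = mse(e$signed_error), mue = mue(e$signed_error),
               maxe = mx$value, maxe_complex = mx$complex_id,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Benchmark density functionals against reference reduction energies
#'
#' The central entry point: given per-functional predictions of dE_elec and
#' the CCSD(T)/CBS references, computes signed errors and per-functional
#' MSE, MUE and MaxE, classifies each functional into accuracy group
#' I/II/III, and ranks them by MUE.
#'
#' @param predictions data frame `functional`, `complex_id`, `delta_e_kcal`.
#' @param references data frame `complex_id`, `delta_e_kcal` (or a
#'   `reference_table` from [build_reference_table()]).
#' @param thresholds a [group_thresholds()].
#' @param metadata optional data frame `functional`, `family`,
#'   `hf_exchange` joined onto the summary (e.g. [dft_functionals()]).
#' @return An object of class `dft_benchmark` with elements `errors`
#'   (signed-error records), `summary` (ranked per-functional statistics),
#'   `thresholds` and `references`.
#' @examples
#' refs <- data.frame(complex_id = c("a", "b"), delta_e_kcal = c(-380, -250))
#' preds <- data.frame(functional = "X", complex_id = c("a", "b"),
#'                     delta_e_kcal = c(-378, -251))
#' fit <- dft_benchmark(preds, refs)
#' summary(fit)
#' @export
dft_benchmark <- function(predictions, references,
                          thresholds = group_thresholds(),
                          metadata = NULL) {
  errors <- signed_errors(predictions, references)
  summ <- .summarise_errors(errors)
  summ$group <- classify_group(summ$mue, thresholds)
  summ <- rank_functionals(summ)
  if (!is.null(metadata)) {
    keep <- intersect(c("functional", "family", "hf_exchange"),
                      names(metadata))
    summ <- merge(summ, metadata[, keep, drop = FALSE],
                  by = "functional", all.x = TRUE, sort = FALSE)
    summ <- summ[order(summ$rank), , drop = FALSE]
    rownames(summ) <- NULL
  }
  structure(list(errors = errors, summary = summ, thresholds = thresholds,
                 references = references),
            class = "dft_benchmark")
}

#' @export
print.dft_benchmark <- function(x, ...) {
  cat("DFT benchmark:", length(unique(x$errors$functional)),
      "functionals over", length(unique(x$errors$complex_id)),
      "complexes\n")
  cat("Group boundaries:",
      format(qty_value(x$thresholds$group1_max), digits = 5), "/",
      format(qty_value(x$thresholds$group2_max), digits = 5),
      "kcal/mol (I / II)\n\n")
  top <- utils::head(x$summary, 10L)
  show <- data.frame(rank = top$rank, functional = top$functional,
                     MSE = .round2(top$mse), MUE = .round2(top$mue),
                     MaxE = .round2(top$maxe), group = top$group)
  print(show, row.names = FALSE)
  if (nrow(x$summary) > 10L) cat("...", nrow(x$summary) - 10L, "more\n")
  invisible(x)
}

#' @export
summary.dft_benchmark <- function(object, ...) {
  object$summary
}

#' @export
coef.dft_benchmark <- function(object, ...) {
  stats::setNames(object$summary$mse, object$summary$functional)
}

#' @export
plot.dft_benchmark <- function(x, ...) {
  s <- x$summary
  bp <- graphics::barplot(s$mue, names.arg = s$functional, las = 2,
                          ylab = "MUE (kcal/mol)",
                          col = c(I = "forestgreen", II = "goldenrod",
                                  III = "firebrick")[s$group], ...)
  graphics::abline(h = qty_value(x$thresholds$group1_max), lty = 2)
  graphics::abline(h = qty_value(x$thresholds$group2_max), lty = 3)
  invisible(bp)
}

#' Render a ranking table for one ligand grouping
#'
#' Restricts a fitted benchmark to one of the ligand groups (A: all-water,
#' B: tetrahedral one-side-chain, C: octahedral one-side-chain) or the full
#' complex set, recomputes the statistics on that subset, and renders a
#' ranked table at 2-dp rounding with one column of signed errors per
#' complex.  Functionals without complete coverage of the subset are
#' dropped.
#'
#' @param bench a [dft_benchmark()] fit.
#' @param grouping `"overall"`, `"A"`, `"B"` or `"C"`.
#' @return A data frame: `rank`, `functional` (plus `family`/`hf_exchange`
#'   when present in the fit), `mue`, `maxe`, then per-complex error
#'   columns; all statistics rounded to 2 dp.
#' @export
report_tables <- function(bench, grouping = c("overall", "A", "B", "C")) {
  stopifnot(inherits(bench, "dft_benchmark"))
  grouping <- match.arg(grouping)
  ids <- if (grouping == "overall") {
    unique(bench$errors$complex_id)
  } else {
    intersect(complex_groups()[[grouping]], bench$errors$complex_id)
  }
  if (length(ids) == 0L) {
    stop("benchmark contains no complexes for grouping ", grouping,
         call. = FALSE)
  }
  err <- bench$errors[bench$errors$complex_id %in% ids, , drop = FALSE]
  cover <- table(err$functional)
  full <- names(cover)[cover == length(ids)]
  if (length(full) == 0L) {
    stop("no functional covers every complex in grouping ", grouping,
         call. = FALSE)
  }
  err <- err[err$functional %in% full, , drop = FALSE]
  summ <- rank_functionals(.summarise_errors(err))
  summ$group <- classify_group(summ$mue, bench$thresholds)
  meta_cols <- intersect(c("family", "hf_exchange"), names(bench$summary))
  if (length(meta_cols)) {
    summ <- merge(summ,
                  bench$summary[, c("functional", meta_cols), drop = FALSE],
                  by = "functional", all.x = TRUE, sort = FALSE)
    summ <- summ[order(summ$rank), , drop = FALSE]
  }
  canon <- iron_complexes()$complex_id
  ids <- c(canon[canon %in% ids], sort(setdiff(ids, canon)))
  wide <- lapply(ids, function(id) {
    e <- err[err$complex_id == id, , drop = FALSE]
    .round2(stats::setNames(e$signed_error, e$functional)[summ$functional])
  })
  names(wide) <- ids
  out <- data.frame(rank = summ$rank, functional = summ$functional,
                    stringsAsFactors = FALSE)
  for (mc in meta_cols) out[[mc]] <- summ[[mc]]
  out$mue <- .round2(summ$mue)
  out$maxe <- .round2(summ$maxe)
  out$group <- summ$group
  for (id in ids) out[[id]] <- unname(wide[[id]])
  rownames(out) <- NULL
  out
}
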