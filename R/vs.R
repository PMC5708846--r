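#' Screening score tables
#'
#' A screen table is a tibble with one row per compound: `id` (unique),
#' `role` (`"active"` or `"decoy"`), `pharmacology` (`"agonist"`,
#' `"inhibitor"` or `"none"`; every active must have one), an optional
#' `chemotype` label, and repeated docking scores in columns
#' `score_1..score_k`. Scores follow the docking-energy convention: lower
#' is more favourable (set `lower_is_better = FALSE` in the ranking
#' functions to flip).
#'
#' @param x A data frame with the columns above.
#' @return A validated `screen_table` tibble.
#' @export
screen_table <- function(x) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("id", "role", "pharmacology") %in% names(x)))
  if (anyDuplicated(x$id)) abort_pf("duplicate compound ids", "data_error")
  if (!all(x$role %in% c("active", "decoy"))) {
    abort_pf("role must be 'active' or 'decoy'", "data_error")
  }
  if (any(x$role == "active" & !x$pharmacology %in% c("agonist", "inhibitor"))) {
    abort_pf("every active needs a pharmacology (agonist/inhibitor)",
             "data_error")
  }
  if (length(score_cols(x)) < 1) {
    abort_pf("need at least one score_<i> column", "data_error")
  }
  if (!"chemotype" %in% names(x)) x$chemotype <- NA_character_
  class(x) <- c("screen_table", class(x))
  x
}

score_cols <- function(x) grep("^score_\\d+$", names(x), value = TRUE)

#' Attribute the best of the repeated docking scores to each compound
#'
#' Docking repeats are aggregated per compound by taking the most
#' favourable score (the minimum under lower-is-better), which is then
#' used for all ranking-based metrics.
#'
#' @param table A [screen_table()].
#' @param lower_is_better Score polarity flag (default `TRUE`).
#' @return The table with a `best_score` column.
#' @export
best_of_repeats <- function(table, lower_is_better = TRUE) {
  sc <- as.matrix(table[, score_cols(table)])
  ok <- rowSums(!is.na(sc)) > 0
  if (!all(ok)) {
    abort_pf(paste0("compound(s) with no score: ",
                    paste(table$id[!ok], collapse = ", ")), "data_error")
  }
  f <- if (lower_is_better) function(r) min(r, na.rm = TRUE) else
    function(r) max(r, na.rm = TRUE)
  table$best_score <- apply(sc, 1, f)
  table
}

# Deterministic ranking: most favourable first, ties by compound id.
rank_screen <- function(table, lower_is_better = TRUE) {
  if (!"best_score" %in% names(table)) {
    table <- best_of_repeats(table, lower_is_better)
  }
  key <- if (lower_is_better) table$best_score else -table$best_score
  table[order(key, table$id), ]
}

roc_points <- function(is_pos) {
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  tibble::tibble(fpr = c(0, cumsum(!is_pos) / n_neg),
                 tpr = c(0, cumsum(is_pos) / n_pos))
}

new_roc <- function(pts, positive, negative, ranked_ids) {
  a <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                              utils::tail(pts$tpr, -1)) / 2)
  structure(pts, class = c("roc_curve", class(pts)),
            positive = positive, negative = negative,
            ranked_ids = ranked_ids, auc = a)
}

#' ROC curve for recovery of actives over decoys
#'
#' Compounds are ranked by best score (most favourable first; ties broken
#' by compound id); the true-positive rate runs over actives and the
#' false-positive rate over decoys.
#'
#' @param table A [screen_table()].
#' @param lower_is_better Score polarity flag.
#' @return A `roc_curve` tibble of `(fpr, tpr)` points from (0,0) to
#'   (1,1), with the trapezoidal `auc` as an attribute.
#' @export
roc_recovery <- function(table, lower_is_better = TRUE) {
  if (!any(table$role == "active") || !any(table$role == "decoy")) {
    abort_pf("recovery ROC needs both actives and decoys", "class_error")
  }
  r <- rank_screen(table, lower_is_better)
  new_roc(roc_points(r$role == "active"), "active", "decoy", r$id)
}

#' ROC curve for pharmacological selectivity
#'
#' Decoys are excluded; positives are the actives of the chosen
#' pharmacology and negatives the actives of the other.
#'
#' @param table A [screen_table()].
#' @param positive `"agonist"` or `"inhibitor"`.
#' @param lower_is_better Score polarity flag.
#' @return A `roc_curve`, as for [roc_recovery()].
#' @export
roc_selectivity <- function(table, positive = c("agonist", "inhibitor"),
                            lower_is_better = TRUE) {
  positive <- match.arg(positive)
  negative <- setdiff(c("agonist", "inhibitor"), positive)
  act <- table[table$role == "active", ]
  n_pos <- sum(act$pharmacology == positive)
  n_neg <- sum(act$pharmacology == negative)
  if (n_pos == 0 || n_neg == 0) {
    abort_pf(paste0("selectivity ROC needs both pharmacology classes; ",
                    "have ", n_pos, " ", positive, "(s) and ", n_neg, " ",
                    negative, "(s)"), "class_error")
  }
  r <- rank_screen(act, lower_is_better)
  new_roc(roc_points(r$pharmacology == positive), positive, negative, r$id)
}

#' Trapezoidal area under a ROC curve
#'
#' @param roc A `roc_curve`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) attr(roc, "auc")

#' Normalised square-root area under the ROC curve (NSQ_AUC)
#'
#' The ROC's true-positive rate is integrated (trapezoid rule) against the
#' square root of the false-positive rate, which up-weights early
#' recovery; the result is normalised so a random ranking (diagonal ROC,
#' square-root area 1/3) scores 0 and a perfect classifier scores 100:
#' `NSQ_AUC = 100 * (A_sq - 1/3) / (1 - 1/3)`. The worst possible ranking
#' scores -50.
#'
#' @param roc A `roc_curve`.
#' @return A number in `[-50, 100]`.
#' @export
nsq_auc <- function(roc) {
  s <- sqrt(roc$fpr)
  a_sq <- sum(diff(s) * (utils::head(roc$tpr, -1) +
                           utils::tail(roc$tpr, -1)) / 2)
  100 * (a_sq - 1 / 3) / (2 / 3)
}

#' Chemotype enrichment factors at fixed library fractions
#'
#' For the top fraction `f` of the ranked library (`n_top = ceiling(f *
#' N)`): `EF = (n_recovered / n_top) / (n_cluster / N)`, i.e. the fold
#' over-representation of that chemotype among the top-ranked compounds;
#' the maximum is `1/f`. Boundary ties are resolved by the deterministic
#' (score, id) ranking. Empty clusters are reported with `EF = NA` and
#' `undefined = TRUE` rather than erroring.
#'
#' @param table A [screen_table()] with chemotype labels on the compounds
#'   of interest.
#' @param fractions Library fractions (default 1, 5 and 10%).
#' @param clusters Chemotype labels to report; defaults to every label
#'   present. The union of all compounds is always reported as `"all"`.
#' @param lower_is_better Score polarity flag.
#' @return An `EnrichmentReport` tibble: `chemotype`, `fraction`, `ef`,
#'   `n_recovered`, `n_cluster`, `n_top`, `undefined`.
#' @export
enrichment_factors <- function(table, fractions = c(0.01, 0.05, 0.10),
                               clusters = NULL, lower_is_better = TRUE) {
  r <- rank_screen(table, lower_is_better)
  n <- nrow(r)
  clusters <- clusters %||% sort(unique(stats::na.omit(r$chemotype)))
  purrr::map_dfr(fractions, function(f) {
    n_top <- ceiling(f * n)
    top <- r[seq_len(n_top), ]
    rows <- purrr::map_dfr(clusters, function(cl) {
      n_cl <- sum(r$chemotype == cl, na.rm = TRUE)
      rec <- sum(top$chemotype == cl, na.rm = TRUE)
      tibble::tibble(chemotype = cl, fraction = f,
                     ef = if (n_cl == 0) NA_real_ else (rec / n_top) / (n_cl / n),
                     n_recovered = rec, n_cluster = n_cl, n_top = n_top,
                     undefined = n_cl == 0)
    })
    dplyr::bind_rows(rows, tibble::tibble(
      chemotype = "all", fraction = f, ef = 1, n_recovered = n_top,
      n_cluster = n, n_top = n_top, undefined = FALSE))
  })
}

#' Rank and percentile of the refinement ligand in a screen
#'
#' @param table A [screen_table()] containing `ligand_id`.
#' @param ligand_id Compound identifier of the refinement ligand.
#' @param lower_is_better Score polarity flag.
#' @return A list with 1-based `rank` and `percentile = rank / N`.
#' @export
refinement_ligand_rank <- function(table, ligand_id, lower_is_better = TRUE) {
  r <- rank_screen(table, lower_is_better)
  pos <- match(ligand_id, r$id)
  if (is.na(pos)) {
    abort_pf(paste0("compound '", ligand_id, "' not in table"), "id_error")
  }
  list(rank = pos, percentile = pos / nrow(r))
}

#' Read / write screen-table CSV
#'
#' Columns: `id, role, pharmacology, chemotype, score_1..score_k`.
#'
#' @param path CSV path.
#' @return A [screen_table()].
#' @export
read_screen_csv <- function(path) {
  screen_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_screen_csv
#' @param table A [screen_table()].
#' @export
write_screen_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @export
tidy.roc_curve <- function(x, ...) tibble::as_tibble(unclass(x)[c("fpr", "tpr")])

#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = roc_auc(x), nsq_auc = nsq_auc(x),
                 positive = attr(x, "positive"),
                 negative = attr(x, "negative"))
}

#' ROC plot
#'
#' @param object A `roc_curve`.
#' @param ... Unused.
#' @return A ggplot object with the NSQ_AUC in the subtitle.
#' @export
autoplot.roc_curve <- function(object, ...) {
  df <- tidy.roc_curve(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = paste0("False positive rate (", attr(object, "negative"), "s)"),
      y = paste0("True positive rate (", attr(object, "positive"), "s)"),
      subtitle = sprintf("NSQ_AUC = %.1f", nsq_auc(object))) +
    ggplot2::theme_minimal()
}

#' Bar chart of chemotype enrichment factors
#'
#' @param report An [enrichment_factors()] tibble.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(report) {
  df <- report[report$chemotype != "all", ]
  df$fraction <- factor(sprintf("EF%d", round(100 * df$fraction)),
                        levels = sprintf("EF%d", sort(unique(round(100 * df$fraction)))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chemotype, y = .data$ef,
                                   fill = .data$fraction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Chemotype cluster", y = "Enrichment factor",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
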