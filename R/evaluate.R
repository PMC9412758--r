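#' Precision, recall and F1 from confusion counts
#'
#' @param tp,fp,fn non-negative counts (vectorized)
#' @return a tibble with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`;
#'   metrics with a zero denominator are `NA` (undefined), never 0
#' @export
metrics_from_counts <- function(tp, fp, fn) {
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & precision + recall > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  tibble(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
         f1 = f1)
}

relation_key_cols <- c("type", "source_code", "source_instance", "side",
                       "target_label", "target_norm", "uncertain")

# per-entry, per-type confusion counts from matched multisets of relation keys
confusion_counts <- function(predicted, gold) {
  for (col in c("entry_id", relation_key_cols)) {
    if (!col %in% names(predicted)) predicted[[col]] <- NA
    if (!col %in% names(gold)) gold[[col]] <- NA
  }
  p <- predicted |> count(across(all_of(c("entry_id", relation_key_cols))),
                          name = "n_pred")
  g <- gold |> count(across(all_of(c("entry_id", relation_key_cols))),
                     name = "n_gold")
  joined <- full_join(p, g, by = c("entry_id", relation_key_cols)) |>
    mutate(n_pred = replace_na(.data$n_pred, 0L),
           n_gold = replace_na(.data$n_gold, 0L),
           tp = pmin(.data$n_pred, .data$n_gold),
           fp = .data$n_pred - .data$tp,
           fn = .data$n_gold - .data$tp)
  joined |>
    group_by(.data$entry_id, .data$type) |>
    summarise(tp = sum(.data$tp), fp = sum(.data$fp), fn = sum(.data$fn),
              .groups = "drop")
}

#' Score predicted relations against a gold standard
#'
#' A true positive requires the relation type, both linked entity
#' identities and the feature values (side of the relative, uncertainty of
#' the condition, onset bounds) to match within the same entry. Returns
#' per-type metrics and a micro-average row aggregating the confusion counts
#' across types.
#'
#' @param predicted,gold relation-key tibbles (see [relation_keys()]), with
#'   an `entry_id` column aligning the two sets
#' @return a list with `by_type` (metric tibble incl. a `micro` row) and
#'   `per_entry` (entry-level confusion counts, the bootstrap resampling
#'   unit)
#' @export
score_relations <- function(predicted, gold) {
  per_entry <- confusion_counts(predicted, gold)
  by_type <- per_entry |>
    group_by(.data$type) |>
    summarise(tp = sum(.data$tp), fp = sum(.data$fp), fn = sum(.data$fn),
              .groups = "drop")
  micro <- summarise(by_type, tp = sum(.data$tp), fp = sum(.data$fp),
                     fn = sum(.data$fn))
  tab <- bind_rows(
    mutate(by_type, relation = .data$type, .before = 1),
    mutate(micro, relation = "micro", .before = 1)) |>
    select(-any_of("type"))
  metrics <- metrics_from_counts(tab$tp, tab$fp, tab$fn)
  out <- bind_cols(tab[, "relation"], metrics)
  list(by_type = out, per_entry = per_entry)
}

#' Micro-averaged metrics from a per-type count table
#'
#' Convenience for reproducing a published metric table: aggregates per-type
#' TP/FP/FN counts and computes the micro-averaged precision/recall/F1.
#'
#' @param counts tibble with columns `tp`, `fp`, `fn` (one row per relation
#'   type)
#' @return a one-row metric tibble
#' @export
micro_average <- function(counts) {
  metrics_from_counts(sum(counts$tp), sum(counts$fp), sum(counts$fn))
}

#' Percentile bootstrap confidence interval for a relation metric
#'
#' Resamples entries (the evaluation unit) with replacement `B` times and
#' takes the percentile interval of the micro metric across resamples.
#' Deterministic under a fixed seed. When the relation counts are too sparse
#' to resample meaningfully (fewer than two entries carry the relation, or
#' more than half the resamples leave the metric undefined), the interval is
#' flagged unavailable.
#'
#' @param per_entry_counts entry-level counts from [score_relations()]
#'   (optionally filtered to one relation type)
#' @param metric `"precision"`, `"recall"` or `"f1"`
#' @param B number of bootstrap resamples (>= 1)
#' @param level coverage level (default 0.95)
#' @param seed integer seed
#' @return a list with `lower`, `upper`, `level`, `B`, `available`
#' @export
bootstrap_ci <- function(per_entry_counts,
                         metric = c("f1", "precision", "recall"),
                         B = 1000, level = 0.95, seed = 1) {
  metric <- match.arg(metric)
  if (B < 1) abort("B must be >= 1", class = "fhh_param_error")
  counts <- per_entry_counts |>
    group_by(.data$entry_id) |>
    summarise(tp = sum(.data$tp), fp = sum(.data$fp), fn = sum(.data$fn),
              .groups = "drop")
  carrying <- sum(counts$tp + counts$fp + counts$fn > 0)
  if (nrow(counts) == 0 || carrying < 2) {
    return(list(lower = NA_real_, upper = NA_real_, level = level, B = B,
                available = FALSE))
  }
  stat <- function(idx) {
    m <- metrics_from_counts(sum(counts$tp[idx]), sum(counts$fp[idx]),
                             sum(counts$fn[idx]))
    m[[metric]]
  }
  vals <- with_seed(seed, {
    n <- nrow(counts)
    vapply(seq_len(B), function(b) stat(sample.int(n, n, replace = TRUE)),
           numeric(1))
  })
  ok <- !is.na(vals)
  if (mean(ok) < 0.5) {
    return(list(lower = NA_real_, upper = NA_real_, level = level, B = B,
                available = FALSE))
  }
  alpha <- (1 - level) / 2
  q <- unname(quantile(vals[ok], c(alpha, 1 - alpha), type = 7))
  list(lower = q[1], upper = q[2], level = level, B = B, available = TRUE)
}

#' Compare structured-only and NLP-augmented screening against gold
#'
#' Eligibility is binary per patient and cohort; precision/recall/F1 are
#' computed per mode from the pooled patient-cohort decisions and bootstrap
#' percentile intervals are taken over patients.
#'
#' @param results_structured,results_augmented,gold_eligibility eligibility
#'   tibbles (columns `patient_id`, `cohort`, `eligible`) over the same
#'   patient set
#' @param B bootstrap resamples
#' @param level coverage level
#' @param seed integer seed
#' @return a tibble with one row per mode and metric columns with CI bounds
#' @export
compare_algorithms <- function(results_structured, results_augmented,
                               gold_eligibility, B = 1000, level = 0.95,
                               seed = 1) {
  key <- function(x) unique(x$patient_id)
  ids <- list(structured = key(results_structured),
              augmented = key(results_augmented),
              gold = key(gold_eligibility))
  all_ids <- Reduce(union, ids)
  missing <- lapply(ids, function(x) setdiff(all_ids, x))
  if (any(lengths(missing) > 0)) {
    msg <- paste0(
      "patient sets are not aligned; missing ids: ",
      paste(vapply(names(missing), function(n) {
        paste0(n, ": [", paste(missing[[n]], collapse = ", "), "]")
      }, character(1)), collapse = "; "))
    abort(msg, class = "fhh_alignment_error")
  }

  score_mode <- function(pred, mode_name) {
    joined <- inner_join(
      pred |> select("patient_id", "cohort", pred = "eligible"),
      gold_eligibility |> select("patient_id", "cohort", gold = "eligible"),
      by = c("patient_id", "cohort"))
    per_patient <- joined |>
      group_by(.data$patient_id) |>
      summarise(tp = sum(.data$pred & .data$gold),
                fp = sum(.data$pred & !.data$gold),
                fn = sum(!.data$pred & .data$gold), .groups = "drop")
    m <- metrics_from_counts(sum(per_patient$tp), sum(per_patient$fp),
                             sum(per_patient$fn))
    cis <- lapply(c("precision", "recall", "f1"), function(met) {
      bootstrap_ci(per_patient |> mutate(entry_id = .data$patient_id,
                                         type = "eligibility"),
                   metric = met, B = B, level = level, seed = seed)
    })
    names(cis) <- c("precision", "recall", "f1")
    tibble(mode = mode_name,
           precision = m$precision,
           precision_lower = cis$precision$lower,
           precision_upper = cis$precision$upper,
           recall = m$recall,
           recall_lower = cis$recall$lower,
           recall_upper = cis$recall$upper,
           f1 = m$f1,
           f1_lower = cis$f1$lower, f1_upper = cis$f1$upper)
  }
  bind_rows(score_mode(results_structured, "STRUCTURED_ONLY"),
            score_mode(results_augmented, "NLP_AUGMENTED"))
}
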