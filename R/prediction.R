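#' Top-k prediction from the ranked database
#'
#' Predicts as activatable the `k` highest-ranked mis-splicing events at a
#' junction (all events when fewer than `k` are present; none when the
#' junction is absent from the database).
#'
#' @param db ranked event data.frame from [build_missplice_db()].
#' @param junction one annotated junction (list or one-row data.frame).
#' @param k number of top events (default 4).
#' @return data.frame of the predicted events (subset of `db` rows).
#' @export
predict_top_k <- function(db, junction, k = 4L) {
  junction <- as.list(junction)
  ev <- db[db$transcript_id == junction$transcript_id &
             db$annotated_donor_pos == junction$donor_pos, , drop = FALSE]
  ev[ev$rank <= k, , drop = FALSE]
}

#' Delta-score prediction under a pluggable scorer
#'
#' For every candidate site in a variant context, computes
#' `delta = score(VAR window) - score(REF window)` and predicts activation
#' when `delta >= threshold` (default 0.1). Unlike the database method,
#' variants creating a brand-new GT/GC are scoreable here. Candidates the
#' scorer fails on are skipped with a warning, never silently scored 0.
#'
#' @param scorer a scorer function: `(character vector of windows) ->
#'   numeric scores in [0, 1]`, with optional attributes `floor` and
#'   `label` (see [df_scorer()]).
#' @param context a `variant_context` from [build_variant_context()].
#' @param threshold delta threshold (default 0.1).
#' @return the context's `sites` data.frame with `ref_score`,
#'   `var_score`, `delta`, `predicted` columns.
#' @export
predict_delta <- function(scorer, context, threshold = 0.1) {
  s <- context$sites
  score_safe <- function(w) {
    out <- rep(NA_real_, length(w))
    ok <- !is.na(w)
    if (any(ok)) {
      res <- tryCatch(scorer(w[ok]), error = function(e) e)
      if (inherits(res, "error")) {
        warning("scorer failed (", conditionMessage(res),
                "); candidates skipped", call. = FALSE)
      } else out[ok] <- res
    }
    out
  }
  s$ref_score <- score_safe(s$ref_window)
  s$var_score <- score_safe(s$var_window)
  # a site whose VAR window disappeared (deleted donor) cannot be activated
  s$var_score[is.na(s$var_window)] <- 0
  s$delta <- s$var_score - s$ref_score
  s$predicted <- !is.na(s$delta) & s$delta >= threshold
  s
}

#' Union of database and delta predictions
#'
#' @param db_offsets,delta_offsets integer vectors of predicted offsets
#'   over the same candidate universe.
#' @return data.frame `offset`, `source` (`"db"`, `"delta"`, `"both"`).
#' @export
predict_union <- function(db_offsets, delta_offsets) {
  offs <- sort(union(db_offsets, delta_offsets))
  data.frame(
    offset = offs,
    source = ifelse(offs %in% db_offsets & offs %in% delta_offsets, "both",
                    ifelse(offs %in% db_offsets, "db", "delta")),
    stringsAsFactors = FALSE
  )
}

#' Sensitivity/specificity of predictions over a candidate universe
#'
#' Candidates are all decoy offsets of a junction plus the true activated
#' cryptic offsets. Sensitivity = TP/(TP+FN) over true cryptics;
#' specificity = TN/(TN+FP) over non-activated decoys. A truth offset
#' missing from the candidate set is a hard error (it means candidate
#' enumeration is broken upstream).
#'
#' @param predicted integer vector of predicted offsets.
#' @param truth integer vector of truly activated offsets.
#' @param candidates integer vector of all candidate offsets.
#' @return one-row data.frame: `tp`, `fn`, `fp`, `tn`, `sensitivity`,
#'   `specificity`.
#' @export
evaluate_prediction <- function(predicted, truth, candidates) {
  if (!all(truth %in% candidates)) {
    stop("truth offset(s) absent from the candidate set: ",
         paste(setdiff(truth, candidates), collapse = ", "), call. = FALSE)
  }
  predicted <- intersect(predicted, candidates)
  decoys <- setdiff(candidates, truth)
  tp <- length(intersect(truth, predicted))
  fn <- length(setdiff(truth, predicted))
  fp <- length(intersect(decoys, predicted))
  tn <- length(setdiff(decoys, predicted))
  data.frame(tp = tp, fn = fn, fp = fp, tn = tn,
             sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
             specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Sweep evaluation over rank cut-offs and delta thresholds
#'
#' Pools true-cryptic and decoy candidates over a set of evaluation cases
#' and reports sensitivity/specificity of the database rule at each rank
#' cut-off `1..k_max`, and of the delta rule at each threshold on a grid.
#' Sensitivity is per-cryptic (pooled), the primary mode; per-case rates
#' can be derived from the returned per-case table.
#'
#' @param cases list of evaluation cases; each is a list with integer
#'   vectors `truth`, `candidates`, `db_ranks` (named by offset: the
#'   database rank of each candidate, NA when absent) and optionally
#'   `delta` (named numeric deltas per candidate).
#' @param k_max largest rank cut-off to sweep.
#' @param delta_grid thresholds for the delta sweep.
#' @return data.frame: `method`, `cutoff`, `tp`, `fn`, `fp`, `tn`,
#'   `sensitivity`, `specificity`.
#' @export
evaluate_sweep <- function(cases, k_max = 10L,
                           delta_grid = seq(0.05, 0.5, by = 0.05)) {
  pool <- function(predict_fun) {
    tot <- c(tp = 0L, fn = 0L, fp = 0L, tn = 0L)
    for (cs in cases) {
      pr <- predict_fun(cs)
      e <- evaluate_prediction(pr, cs$truth, cs$candidates)
      tot <- tot + c(tp = e$tp, fn = e$fn, fp = e$fp, tn = e$tn)
    }
    data.frame(tp = tot[["tp"]], fn = tot[["fn"]], fp = tot[["fp"]],
               tn = tot[["tn"]],
               sensitivity = tot[["tp"]] / max(1L, tot[["tp"]] + tot[["fn"]]),
               specificity = tot[["tn"]] / max(1L, tot[["tn"]] + tot[["fp"]]))
  }
  rows <- list()
  for (k in seq_len(k_max)) {
    r <- pool(function(cs) {
      rk <- cs$db_ranks
      as.integer(names(rk))[!is.na(rk) & rk <= k]
    })
    rows[[length(rows) + 1L]] <- cbind(method = "db_topk", cutoff = k, r)
  }
  has_delta <- all(vapply(cases, function(cs) !is.null(cs$delta),
                          logical(1)))
  if (has_delta) {
    for (th in delta_grid) {
      r <- pool(function(cs) {
        d <- cs$delta
        as.integer(names(d))[!is.na(d) & d >= th]
      })
      rows[[length(rows) + 1L]] <- cbind(method = "delta", cutoff = th, r)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Categorise how a variant changed a donor's strength
#'
#' Based on the VAR/REF score ratio: `< 0.5` "weaker by >50%",
#' `[0.5, 0.9)` "weaker by 10-50%", `[0.9, 1.1]` "unchanged", `> 1.1`
#' "stronger by >10%"; a site scored 0 in REF but positive in VAR is
#' "created", the reverse "abolished", both zero "unscored". Vectorised.
#'
#' @param ref_score,var_score numeric scores (>= 0).
#' @return character vector of categories.
#' @export
categorize_strength_change <- function(ref_score, var_score) {
  n <- max(length(ref_score), length(var_score))
  r <- rep_len(ref_score, n); v <- rep_len(var_score, n)
  out <- rep(NA_character_, n)
  both0 <- r == 0 & v == 0
  created <- r == 0 & v > 0
  abolished <- r > 0 & v == 0
  rat <- ifelse(r > 0, v / r, NA_real_)
  out[both0] <- "unscored"
  out[created] <- "created"
  out[abolished] <- "abolished"
  rest <- !(both0 | created | abolished)
  out[rest & rat < 0.5] <- "weaker by >50%"
  out[rest & rat >= 0.5 & rat < 0.9] <- "weaker by 10-50%"
  out[rest & rat >= 0.9 & rat <= 1.1] <- "unchanged"
  out[rest & rat > 1.1] <- "stronger by >10%"
  out
}

#' Strength comparisons for activated cryptic donors
#'
#' For each true cryptic in a scored variant context: is it stronger than
#' the variant-weakened annotated donor; is it the strongest site within
#' the scan window (versus all decoys and the annotated VAR); is it
#' recognised at all (score above the scorer's floor)?
#'
#' @param context a `variant_context`.
#' @param scorer a scorer function (see [predict_delta()]).
#' @return data.frame, one row per cryptic: `offset`,
#'   `stronger_than_annotated_var`, `strongest_within_window`,
#'   `recognised`.
#' @export
strength_comparisons <- function(context, scorer) {
  floor_ <- attr(scorer, "floor") %||% 0
  s <- predict_delta(scorer, context, threshold = Inf)  # just for scores
  ann_var <- context$annotated
  ann_var_score <- if (ann_var$var_absent || is.na(ann_var$var_window)) 0
                   else scorer(ann_var$var_window)
  cr <- s[s$kind == "cryptic", , drop = FALSE]
  if (nrow(cr) == 0L) {
    return(data.frame(offset = integer(0),
                      stronger_than_annotated_var = logical(0),
                      strongest_within_window = logical(0),
                      recognised = logical(0)))
  }
  all_var <- c(s$var_score, ann_var_score)
  data.frame(
    offset = cr$offset_ref,
    stronger_than_annotated_var = cr$var_score > ann_var_score,
    strongest_within_window =
      cr$var_score >= max(all_var, na.rm = TRUE),
    recognised = cr$var_score > floor_
  )
}
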