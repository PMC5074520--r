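# In-silico SNP analysis of the start-site flanking context: each mutable
# position of the context window is substituted by the three alternative
# nucleotides, the affected features are recalculated and the trained model
# is re-applied, reporting IC_difference = IC_mutation - IC_wildtype.

# Feature vector of one candidate with the model's PWMs applied.
candidate_feature_vector <- function(tx, candidate, model, efficiency,
                                     pair = NULL, mfe_engine = mfe_nussinov) {
  v <- extract_features(tx, candidate, pair, efficiency,
                        pwm_model = model$pwm, mfe_engine = mfe_engine,
                        window = if (is.null(model$window)) 99L else model$window)
  matrix(v, nrow = 1, dimnames = list(NULL, names(v)))
}

#' Predict initiation confidences for candidates of one or more transcripts
#'
#' @param model A `tis_model` with an embedded PWM and threshold.
#' @param transcripts Named list of [transcript()] objects.
#' @param candidates Candidate data frame ([enumerate_candidates()]).
#' @param efficiency `tis_efficiency`.
#' @param pairs Optional named list of `tis_ortholog_pair`.
#' @param mfe_engine Folding engine.
#' @return `candidates` with added columns `confidence` and `class`.
#' @export
predict_candidates <- function(model, transcripts, candidates, efficiency,
                               pairs = NULL, mfe_engine = mfe_nussinov) {
  if (!nrow(candidates)) {
    candidates$confidence <- numeric(0)
    candidates$class <- character(0)
    return(candidates)
  }
  conf <- vapply(seq_len(nrow(candidates)), function(r) {
    tx <- transcripts[[candidates$transcript_id[r]]]
    pr <- if (!is.null(pairs)) pairs[[tx$id]] else NULL
    X <- candidate_feature_vector(tx, candidates[r, ], model, efficiency,
                                  pr, mfe_engine)
    predict_confidence(model, X)
  }, numeric(1))
  candidates$confidence <- conf
  candidates$class <- confidence_class(conf, model$threshold)
  candidates
}

# Mutable Kozak positions of the SNP window. The default ("extended") window
# is the PWM context window: 15 nt upstream + 10 nt downstream of the codon,
# 25 positions -> 75 variant contexts. "literal" restricts downstream to
# +4..+10 (22 positions, 66 contexts). The codon itself is never mutated.
snp_positions <- function(window_mode = c("extended", "literal")) {
  c(-CONTEXT_UP:-1, 4:(3 + context_down(match.arg(window_mode))))
}

#' In-silico SNP scan of one candidate's flanking context
#'
#' Substitutes every mutable context position by the three alternative
#' nucleotides, recomputes the sequence features on the mutated transcript
#' and re-applies the model. Conservation features are recomputed against
#' the mutated sequence by default (`conservation = "recompute"`) or frozen
#' at their wildtype values (`"frozen"`). Folding energies are memoised by
#' window sequence, so unaffected windows are reused; `recompute = "full"`
#' disables the cache (results are identical by construction).
#'
#' @param tx A [transcript()].
#' @param candidate One candidate row.
#' @param model A `tis_model` with PWM and threshold.
#' @param efficiency `tis_efficiency`.
#' @param pair Optional `tis_ortholog_pair` for the transcript.
#' @param window_mode `"extended"` (default, 25 mutable positions) or
#'   `"literal"` (22).
#' @param conservation `"recompute"` (default) or `"frozen"`.
#' @param recompute `"incremental"` (default; memoised windows) or `"full"`.
#' @return Object of class `tis_mutmatrix`: `confidence` and `ic_difference`
#'   (4 x n-position matrices, rows A/C/G/U, wildtype cells carry the
#'   wildtype confidence and difference 0), `above_threshold` mask,
#'   `wildtype_confidence`, `positions`, `wildtype_nt`, `candidate`.
#' @export
snp_scan <- function(tx, candidate, model, efficiency, pair = NULL,
                     window_mode = c("extended", "literal"),
                     conservation = c("recompute", "frozen"),
                     recompute = c("incremental", "full")) {
  window_mode <- match.arg(window_mode)
  conservation <- match.arg(conservation)
  recompute <- match.arg(recompute)
  engine <- if (recompute == "incremental") mfe_cached(mfe_nussinov) else mfe_nussinov
  i0 <- tx$cds_start + candidate$position
  qs <- snp_positions(window_mode)
  idx <- kozak_index(i0, qs)
  if (any(idx < 1L | idx > nchar(tx$sequence))) {
    stop("context window extends beyond the transcript")
  }
  wt_X <- candidate_feature_vector(tx, candidate, model, efficiency, pair,
                                   engine)
  wt_conf <- predict_confidence(model, wt_X)
  cons_slots <- c("utr_conservation", "codon_conserved", "aa_conserved")
  wt_nt <- substring(tx$sequence, idx, idx)
  cand_m <- candidate
  cand_m$orf_length_nt <- NA_integer_   # re-derived on the mutated sequence
  conf <- matrix(NA_real_, nrow = 4, ncol = length(qs),
                 dimnames = list(NT, qs))
  for (ci in seq_along(qs)) {
    conf[wt_nt[ci], ci] <- wt_conf
    for (nt in setdiff(NT, wt_nt[ci])) {
      seq_m <- tx$sequence
      substr(seq_m, idx[ci], idx[ci]) <- nt
      tx_m <- transcript(tx$id, seq_m, tx$cds_start)
      pair_m <- if (is.null(pair) || !isTRUE(pair$has_ortholog)) {
        NULL
      } else if (conservation == "recompute") {
        align_orthologs(tx_m, pair$ortholog)
      } else {
        NULL
      }
      X <- candidate_feature_vector(tx_m, cand_m, model, efficiency,
                                    pair_m, engine)
      if (conservation == "frozen") {
        X[, cons_slots] <- wt_X[, cons_slots]
      }
      conf[nt, ci] <- predict_confidence(model, X)
    }
  }
  diff <- conf - wt_conf
  diff[cbind(match(wt_nt, NT), seq_along(qs))] <- 0
  structure(
    list(candidate = candidate, positions = qs, wildtype_nt = wt_nt,
         wildtype_confidence = wt_conf, confidence = conf,
         ic_difference = diff,
         above_threshold = conf >= model$threshold),
    class = "tis_mutmatrix"
  )
}

#' @export
print.tis_mutmatrix <- function(x, ...) {
  cat("<tis_mutmatrix> ", x$candidate$codon, " at ", x$candidate$position,
      ": wildtype confidence ", round(x$wildtype_confidence, 3), ", ",
      sum(!is.na(x$ic_difference)) - length(x$positions),
      " variant contexts\n", sep = "")
  invisible(x)
}

#' Summarize SNP scans across candidates
#'
#' For every (position, substituted nucleotide) cell, computes the median
#' and quartiles of IC_difference across the supplied mutation matrices
#' (wildtype cells are not mutations and are excluded), in a long format
#' suitable for per-position boxplots.
#'
#' @param matrices List of `tis_mutmatrix` objects (same window).
#' @return Data frame with columns `position`, `nt`, `n`, `q25`, `median`,
#'   `q75`.
#' @export
summarize_scan <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  qs <- matrices[[1]]$positions
  out <- expand.grid(nt = NT, position = qs, stringsAsFactors = FALSE)
  stats_ <- t(apply(out, 1, function(row) {
    vals <- unlist(lapply(matrices, function(m) {
      ci <- match(as.integer(row[["position"]]), m$positions)
      if (m$wildtype_nt[ci] == row[["nt"]]) return(NULL)
      m$ic_difference[row[["nt"]], ci]
    }))
    if (!length(vals)) return(c(n = 0, q25 = NA, median = NA, q75 = NA))
    c(n = length(vals), q25 = unname(stats::quantile(vals, 0.25)),
      median = stats::median(vals), q75 = unname(stats::quantile(vals, 0.75)))
  }))
  cbind(out[, c("position", "nt")], as.data.frame(stats_))
}

#' Write a mutation matrix as CSV
#'
#' Writes two CSVs: the predicted-confidence matrix and the IC-difference
#' matrix (rows A/C/G/U, one column per mutable position).
#'
#' @param m A `tis_mutmatrix`.
#' @param prefix Output path prefix; files `<prefix>_confidence.csv` and
#'   `<prefix>_ic_difference.csv` are written.
#' @export
write_mutation_matrix <- function(m, prefix) {
  utils::write.csv(m$confidence, paste0(prefix, "_confidence.csv"))
  utils::write.csv(m$ic_difference, paste0(prefix, "_ic_difference.csv"))
  invisible(prefix)
}
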